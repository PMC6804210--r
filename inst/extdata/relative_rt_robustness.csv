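factor,condition,chlorogenic_acid,liquiritin,rutin,isochlorogenic_acid_A,forsythin,glycyrrhizic_acid
instrument_column,LC-20ADXR XBridge BEH,0.3266,0.7457,0.8031,1.0795,1.4729,1.7978
instrument_column,LC-20ADXR ACQUITY BEH C18,0.312,0.7207,0.7781,1.0767,1.4735,1.8311
instrument_column,LC-20ADXR Accucore C18,0.3355,0.7226,0.8161,1.077,1.4618,1.8072
instrument_column,Waters XBridge BEH,0.317,0.685,0.8006,1.0249,1.4906,1.8084
instrument_column,Waters ACQUITY BEH C18,0.3073,0.6584,0.8559,1.0756,1.4719,1.8065
instrument_column,Waters Accucore C18,0.2969,0.6528,0.8671,1.0801,1.5891,1.7856
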