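factor,statistic,chlorogenic_acid,liquiritin,rutin,isochlorogenic_acid_A,forsythin,glycyrrhizic_acid
instrument_column,mean,0.3158,0.6975,0.8201,1.0689,1.4933,1.8061
instrument_column,rsd_pct,4.36,5.42,4.21,2.03,3.21,0.83
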