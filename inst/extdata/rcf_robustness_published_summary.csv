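factor,statistic,chlorogenic_acid,liquiritin,rutin,isochlorogenic_acid_A,forsythin,glycyrrhizic_acid
instrument_column,mean,0.4841,1.2069,0.4773,0.4804,5.636,1.0076
instrument_column,rsd_pct,2.06,3.21,1.89,1.37,3.81,5.57
flow_rate,mean,0.4902,1.1792,0.4855,0.4844,5.0487,0.8539
flow_rate,rsd_pct,0.62,0.61,0.23,0.95,0.62,0.14
injection_volume,mean,0.4866,1.1744,0.4862,0.4876,5.2068,0.8531
injection_volume,rsd_pct,1.62,0.7,0.69,2.68,4.29,0.19
column_temperature,mean,0.49,1.183,0.4871,0.4872,5.0241,0.854
column_temperature,rsd_pct,0.64,0.7,0.46,1.04,0.12,0.08
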