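compound,precision_rsd_pct,stability_rsd_pct,repeatability_rsd_pct,recovery_mean_pct,recovery_rsd_pct
chlorogenic_acid,2.8,2.63,1.52,99.6,2.11
liquiritin,3.2,2.64,3.94,95.11,0.34
rutin,1.2,1.06,0.85,104.19,1.83
forsythoside_A,0.42,0.32,0.61,90.87,2.66
isochlorogenic_acid_A,3.2,1.77,3.79,99.47,1.7
forsythin,0.64,0.98,3.45,100.76,1.86
glycyrrhizic_acid,0.14,0.14,0.36,95,4.24
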