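compound,slope,intercept,linear_low_ug_ml,linear_high_ug_ml,r_squared,lod_ug_ml,loq_ug_ml
chlorogenic_acid,2e+07,2015.5,4.554,145.7,1,0.0861,0.2869
liquiritin,6e+06,-2903.9,10.71,342.8,1,0.0701,0.2335
rutin,2e+07,-1765.6,11.16,357.1,1,0.1003,0.3342
forsythoside_A,8e+06,1164.7,81.52,2608,1,0.0464,0.1546
isochlorogenic_acid_A,2e+07,-1940.5,2.232,71.43,1,0.1034,0.372
forsythin,1e+06,11002,36.79,1177,0.9998,0.0287,0.0956
glycyrrhizic_acid,9e+06,176.68,21.96,702.9,1,0.8994,3.6607
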