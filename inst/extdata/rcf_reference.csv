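compound,rcf
chlorogenic_acid,0.486
liquiritin,1.1992
rutin,0.4872
isochlorogenic_acid_A,0.4852
forsythin,5.0971
glycyrrhizic_acid,0.8563
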