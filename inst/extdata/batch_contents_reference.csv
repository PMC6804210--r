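sample,compound,esm_ug_ml,qams_ug_ml,re_pct
S1,forsythoside_A,540.9,NA,NA
S1,chlorogenic_acid,24.3,23.4,-3.69
S1,liquiritin,56.6,55.5,-1.99
S1,rutin,57.3,55.3,-3.49
S1,isochlorogenic_acid_A,259.9,262.4,0.95
S1,forsythin,235.4,228.1,-3.1
S1,glycyrrhizic_acid,132.9,128,-3.69
S2,forsythoside_A,545.4,NA,NA
S2,chlorogenic_acid,25.3,24.4,-3.73
S2,liquiritin,57.8,56.6,-1.95
S2,rutin,57.9,55.9,-3.48
S2,isochlorogenic_acid_A,262.1,264.6,0.95
S2,forsythin,234.9,227.6,-3.08
S2,glycyrrhizic_acid,132.5,127.6,-3.69
S3,forsythoside_A,527.7,NA,NA
S3,chlorogenic_acid,23.6,22.7,-3.66
S3,liquiritin,52.3,51.2,-2.11
S3,rutin,57.7,55.7,-3.49
S3,isochlorogenic_acid_A,253.6,256,0.95
S3,forsythin,237.2,229.7,-3.14
S3,glycyrrhizic_acid,124.6,120,-3.69
S4,forsythoside_A,534.3,NA,NA
S4,chlorogenic_acid,22.9,22.1,-3.63
S4,liquiritin,51,49.9,-2.15
S4,rutin,57.3,55.3,-3.49
S4,isochlorogenic_acid_A,256.7,259.2,0.95
S4,forsythin,246,237.7,-3.35
S4,glycyrrhizic_acid,124.6,120,-3.69
S5,forsythoside_A,589,NA,NA
S5,chlorogenic_acid,25.5,24.5,-3.73
S5,liquiritin,56.5,55.3,-1.99
S5,rutin,68.5,66.2,-3.42
S5,isochlorogenic_acid_A,283,285.7,0.96
S5,forsythin,238.4,230.9,-3.17
S5,glycyrrhizic_acid,133.5,128.5,-3.69
S6,forsythoside_A,587.7,NA,NA
S6,chlorogenic_acid,25.1,24.1,-3.71
S6,liquiritin,55.7,54.5,-2.01
S6,rutin,68.7,66.4,-3.42
S6,isochlorogenic_acid_A,282.4,285.1,0.96
S6,forsythin,243.9,235.9,-3.3
S6,glycyrrhizic_acid,133.9,129,-3.69
S7,forsythoside_A,586.8,NA,NA
S7,chlorogenic_acid,23.8,23,-3.67
S7,liquiritin,56.4,55.3,-1.99
S7,rutin,66.3,64,-3.43
S7,isochlorogenic_acid_A,281.9,284.7,0.96
S7,forsythin,259.6,250.1,-3.65
S7,glycyrrhizic_acid,133.1,128.2,-3.69
S8,forsythoside_A,590.2,NA,NA
S8,chlorogenic_acid,25.3,24.4,-3.72
S8,liquiritin,61,59.8,-1.87
S8,rutin,67.7,65.4,-3.43
S8,isochlorogenic_acid_A,283.6,286.3,0.96
S8,forsythin,263.7,253.8,-3.73
S8,glycyrrhizic_acid,132.9,128,-3.69
S9,forsythoside_A,600.8,NA,NA
S9,chlorogenic_acid,24.4,23.5,-3.69
S9,liquiritin,56.5,55.4,-1.98
S9,rutin,66.9,64.6,-3.43
S9,isochlorogenic_acid_A,288.7,291.5,0.96
S9,forsythin,254.6,245.6,-3.54
S9,glycyrrhizic_acid,134.3,129.3,-3.69
S10,forsythoside_A,592.9,NA,NA
S10,chlorogenic_acid,24.9,23.9,-3.71
S10,liquiritin,59.9,58.7,-1.9
S10,rutin,68.1,65.8,-3.42
S10,isochlorogenic_acid_A,284.9,287.7,0.96
S10,forsythin,239.1,231.5,-3.18
S10,glycyrrhizic_acid,134.3,129.3,-3.69
S11,forsythoside_A,594.4,NA,NA
S11,chlorogenic_acid,23.6,22.8,-3.66
S11,liquiritin,90.3,89,-1.41
S11,rutin,62.9,60.7,-3.45
S11,isochlorogenic_acid_A,285.6,288.4,0.96
S11,forsythin,229,222.3,-2.92
S11,glycyrrhizic_acid,254.9,245.5,-3.7
S12,forsythoside_A,594,NA,NA
S12,chlorogenic_acid,22.4,21.6,-3.6
S12,liquiritin,89.7,88.4,-1.42
S12,rutin,63.1,60.9,-3.45
S12,isochlorogenic_acid_A,285.4,288.2,0.96
S12,forsythin,230.1,223.3,-2.95
S12,glycyrrhizic_acid,254.1,244.7,-3.7
S13,forsythoside_A,582.4,NA,NA
S13,chlorogenic_acid,23.5,22.6,-3.65
S13,liquiritin,91.2,89.9,-1.4
S13,rutin,76,73.4,-3.39
S13,isochlorogenic_acid_A,279.8,282.5,0.96
S13,forsythin,208.4,203.6,-2.32
S13,glycyrrhizic_acid,253.2,243.8,-3.7
S14,forsythoside_A,555.1,NA,NA
S14,chlorogenic_acid,21.8,21,-3.58
S14,liquiritin,84.2,82.9,-1.48
S14,rutin,60,57.9,-3.47
S14,isochlorogenic_acid_A,266.8,269.3,0.96
S14,forsythin,220.4,214.4,-2.69
S14,glycyrrhizic_acid,232.6,224,-3.7
S15,forsythoside_A,550.4,NA,NA
S15,chlorogenic_acid,21.4,20.6,-3.55
S15,liquiritin,84.7,83.4,-1.48
S15,rutin,60,58,-3.47
S15,isochlorogenic_acid_A,264.5,267.1,0.96
S15,forsythin,189.1,186,-1.64
S15,glycyrrhizic_acid,232.5,223.9,-3.7
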