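factor,condition,chlorogenic_acid,liquiritin,rutin,isochlorogenic_acid_A,forsythin,glycyrrhizic_acid
instrument_column,LC-20ADXR XBridge BEH,0.4761,1.1711,0.4869,0.4817,5.7452,1.0605
instrument_column,LC-20ADXR ACQUITY BEH C18,0.4768,1.2412,0.4695,0.4822,5.3664,1.0167
instrument_column,LC-20ADXR Accucore C18,0.4729,1.1699,0.4836,0.4877,5.9337,1.0145
instrument_column,Waters-ACQUITY XBridge BEH,0.4962,1.2409,0.466,0.4813,5.7142,1.0712
instrument_column,Waters-ACQUITY ACQUITY BEH C18,0.4896,1.1736,0.4854,0.4813,5.4095,0.9405
instrument_column,Waters-ACQUITY Accucore C18,0.4929,1.2445,0.4726,0.4679,5.647,0.9422
flow_rate,0.38,0.4899,1.1855,0.4853,0.4859,5.0013,0.8557
flow_rate,0.39,0.485,1.182,0.4857,0.4859,5.0234,0.8547
flow_rate,0.41,0.4892,1.1683,0.4855,0.4878,5.0544,0.8537
flow_rate,0.42,0.4913,1.1866,0.4861,0.4896,5.0579,0.8537
flow_rate,0.43,0.4943,1.1734,0.4869,0.4789,5.0654,0.8534
flow_rate,0.45,0.4914,1.1796,0.4836,0.4787,5.0895,0.8521
injection_volume,0.2,0.4928,1.1718,0.4936,0.4838,4.8557,0.8565
injection_volume,0.5,0.4925,1.1895,0.4887,0.5191,4.9608,0.8528
injection_volume,1,0.4682,1.1847,0.4842,0.4822,5.0616,0.8516
injection_volume,2,0.4883,1.1722,0.4852,0.4878,5.2151,0.8515
injection_volume,3,0.4863,1.1699,0.4843,0.4857,5.3242,0.8518
injection_volume,4,0.4902,1.1704,0.4841,0.4804,5.3746,0.853
injection_volume,5,0.4851,1.1658,0.4843,0.4822,5.404,0.8533
injection_volume,6,0.4889,1.171,0.4851,0.4792,5.4585,0.8541
column_temperature,28,0.4912,1.1719,0.4849,0.4915,5.0145,0.8536
column_temperature,29,0.4854,1.1922,0.4857,0.4872,5.0184,0.8549
column_temperature,30,0.4951,1.1719,0.4851,0.4937,5.0272,0.8532
column_temperature,31,0.488,1.1894,0.4898,0.4817,5.0303,0.8546
column_temperature,32,0.488,1.1894,0.4898,0.4817,5.0303,0.8546
column_temperature,33,0.4912,1.1838,0.4886,0.4832,5.0215,0.8537
column_temperature,35,0.4913,1.1821,0.4858,0.4914,5.0267,0.8533
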