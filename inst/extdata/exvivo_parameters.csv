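id,c1_kPa,D1_kPa,D2,K1_kPa,K2,theta_deg,r_squared
AD1,2.6970,15.1322,0.9272,2.1722,0.9338,5.56,0.9898
AD2,0.4730,12.0210,0.9184,0.2379,1.3761,12.43,0.9684
AD3,0.6100,6.2073,2.2917,1.5853,10.2653,8.07,0.9795
AD4,0.5100,6.2066,2.1138,0.8650,15.1746,7.79,0.9629
AD5,0.9800,22.9048,0.8946,0.0100,0.0105,40.01,0.9188
N1,0.0101,29.3547,0.5745,1.3323,1.0643,5.80,0.9903
N2,1.0000,14.4936,1.4818,0.1000,0.5000,39.56,0.9478
N3,0.5400,12.1538,1.5536,0.0100,0.0100,14.95,0.9211
N4,1.6478,17.6785,1.0153,0.3353,2.7247,12.00,0.9829
N5,18.3579,5.1581,1.9418,1.1775,4.5227,9.60,0.9905
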