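c1_kPa,D1_kPa,D2,K1_kPa,K2,theta_deg
2.6373,15.2031,0.9696,2.2732,0.9018,5.82
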