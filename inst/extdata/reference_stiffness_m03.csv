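id,c1_kPa,D1_kPa,K1_kPa,K2,theta_deg,AI,YMc_kPa,YMa_kPa,RE_YMc_pct,RE_YMa_pct
AD1,1.6615,9.5780,1.4321,0.9018,5.82,0.23,118.82,94.31,-34.52,-34.01
AD2,1.4505,8.3617,1.2503,0.9018,5.82,0.23,103.73,82.33,-1.11,-17.72
AD3,3.1747,18.3015,2.7365,8.2018,5.82,1.22,745.23,180.20,-22.39,12.53
AD4,34.7756,200.4725,29.9748,0.9018,5.82,0.23,2486.87,1973.87,-27.15,1281.57
AD5,2.3735,13.6828,2.0459,0.9018,44.82,0.00,142.16,141.96,-20.38,-20.47
N1,1.5831,9.1264,1.3646,0.9018,5.82,0.23,113.21,89.86,-30.66,-35.23
N2,2.5951,14.9599,2.2368,0.9018,5.82,0.23,185.58,147.30,-11.04,-29.30
N3,2.2042,12.7068,1.8999,0.9018,5.82,0.23,157.63,125.11,-28.33,-43.05
N4,1.6335,9.4168,1.4080,0.9018,5.82,0.23,116.82,92.72,-35.98,-46.08
N5,2.8693,16.5410,2.4732,2.0018,5.82,0.31,222.09,162.86,-28.36,-32.69
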