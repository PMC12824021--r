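id,c1_kPa,D1_kPa,K1_kPa,K2,theta_deg,AI,YMc_kPa,YMa_kPa,RE_YMc_pct,RE_YMa_pct
AD1,1.8879,10.5925,1.5206,0.9338,5.56,0.23,126.38,100.05,-30.35,-30.00
AD2,1.5950,8.9489,1.2846,0.9338,5.56,0.23,106.77,84.52,1.79,-15.53
AD3,3.3416,18.7487,2.6914,7.9338,5.56,1.18,683.32,177.08,-28.84,10.58
AD4,36.4397,204.4523,29.3495,1.9338,5.56,0.30,2621.01,1931.02,-23.22,1251.57
AD5,2.4893,13.9670,2.0050,0.9338,40.56,0.03,141.75,136.97,-20.61,-23.27
N1,1.7140,9.6165,1.3805,0.9338,5.56,0.23,114.37,90.54,-29.95,-34.74
N2,2.8696,16.1006,2.3113,0.9338,5.56,0.23,192.10,152.07,-7.91,-27.01
N3,2.3830,13.3705,1.9194,0.9338,5.56,0.23,159.53,126.29,-30.86,-42.51
N4,1.8178,10.1991,1.4641,0.9338,5.56,0.23,121.68,96.33,-33.31,-43.98
N5,2.9743,16.6877,2.3956,1.9338,5.56,0.30,213.93,157.61,-30.99,-34.86
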