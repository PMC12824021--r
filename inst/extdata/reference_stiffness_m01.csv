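id,S_pct,k,YMc_invivo_kPa,YMa_invivo_kPa,AI_invivo,YMc_exvivo_kPa,YMa_exvivo_kPa,AI_exvivo,RE_YMc_pct,RE_YMa_pct
AD1,68.27,0.70,126.38,100.05,0.23,181.46,142.92,0.24,-30.35,-30.00
AD2,63.32,0.93,96.99,93.06,0.04,104.90,100.06,0.05,-7.54,-7.00
AD3,81.71,0.98,803.96,161.31,1.33,960.24,160.14,1.43,-16.28,0.73
AD4,82.52,1.22,3247.44,179.87,1.79,3413.61,142.87,1.84,-4.87,25.90
AD5,85.38,0.90,167.17,167.15,0.00,178.56,178.51,0.00,-6.38,-6.37
N1,57.76,0.67,108.67,92.67,0.16,163.27,138.73,0.16,-33.44,-33.20
N2,70.28,0.81,174.49,174.27,0.00,208.60,208.35,0.00,-16.35,-16.35
N3,80.98,0.96,181.07,180.96,0.00,219.94,219.68,0.00,-20.76,-17.63
N4,71.51,0.96,173.46,164.92,0.05,182.46,171.96,0.06,-4.93,-4.09
N5,82.41,0.90,270.60,217.57,0.22,310.02,241.95,0.25,-12.71,-10.08
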