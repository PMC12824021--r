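id,age_years,sex,pressure_sys_mmHg,pressure_dia_mmHg,thickness_mm,perimeter_min_cm,perimeter_max_cm
AD1,48,M,133,76,2.42,12.62,13.88
AD2,57,M,119,65,1.74,13.43,14.48
AD3,61,M,136,91,2.51,11.10,11.72
AD4,58,F,140,91,2.80,9.60,9.89
AD5,55,M,113,60,1.29,10.58,12.96
N1,37,M,88,47,1.66,8.50,9.69
N2,32,M,117,61,1.33,9.19,10.58
N3,42,M,79,45,1.31,9.16,10.33
N4,45,F,111,61,1.44,9.18,9.97
N5,54,M,97,59,1.20,9.94,10.89
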