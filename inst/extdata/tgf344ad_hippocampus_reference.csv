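compartment,group,parameter,mean,sd
total,nonTg,v_mm3,46.40,4.11
total,nonTg,n_cap,1228668,358030
total,nonTg,n_endp,622140,178329
total,nonTg,nv_per_mm3,27147,9990
total,nonTg,nvendp_per_mm3,13742,4996
total,nonTg,l_m,75.99,22.81
total,nonTg,lv_m_per_mm3,1.67,0.60
total,nonTg,mean_len_um,62,9
total,nonTg,rdiff_um,7.19,1.36
total,Tg,v_mm3,49.12,6.39
total,Tg,n_cap,932315,262556
total,Tg,n_endp,472076,131335
total,Tg,nv_per_mm3,19220,5823
total,Tg,nvendp_per_mm3,9732,2918
total,Tg,l_m,82.80,19.09
total,Tg,lv_m_per_mm3,1.72,0.50
total,Tg,mean_len_um,95,40
total,Tg,rdiff_um,7.01,1.16
CA23,nonTg,v_mm3,2.00,0.56
CA23,nonTg,vol_fraction_pct,4.37,1.41
CA23,nonTg,n_cap,77976,33907
CA23,nonTg,n_endp,39345,16963
CA23,nonTg,nv_per_mm3,39872,19819
CA23,nonTg,nvendp_per_mm3,20127,9925
CA23,nonTg,l_m,3.55,0.46
CA23,nonTg,lv_m_per_mm3,1.87,0.45
CA23,nonTg,mean_len_um,58,36
CA23,nonTg,rdiff_um,6.65,0.86
CA23,Tg,v_mm3,1.40,0.45
CA23,Tg,vol_fraction_pct,2.81,0.77
CA23,Tg,n_cap,90070,69728
CA23,Tg,n_endp,45691,34983
CA23,Tg,nv_per_mm3,62976,42192
CA23,Tg,nvendp_per_mm3,32049,21151
CA23,Tg,l_m,4.49,3.04
CA23,Tg,lv_m_per_mm3,3.03,1.75
CA23,Tg,mean_len_um,59,42
CA23,Tg,rdiff_um,5.62,1.49
CA1,nonTg,v_mm3,1.56,0.23
CA1,nonTg,vol_fraction_pct,3.36,0.38
CA1,nonTg,n_cap,253061,299613
CA1,nonTg,n_endp,126891,149786
CA1,nonTg,nv_per_mm3,145097,156826
CA1,nonTg,nvendp_per_mm3,72785,78371
CA1,nonTg,l_m,2.94,0.53
CA1,nonTg,lv_m_per_mm3,1.90,0.39
CA1,nonTg,mean_len_um,41,36
CA1,nonTg,rdiff_um,6.54,0.66
CA1,Tg,v_mm3,1.29,0.44
CA1,Tg,vol_fraction_pct,2.62,0.75
CA1,Tg,n_cap,28355,8444
CA1,Tg,n_endp,19218,5638
CA1,Tg,nv_per_mm3,22542,4723
CA1,Tg,nvendp_per_mm3,15292,3193
CA1,Tg,l_m,3.08,0.77
CA1,Tg,lv_m_per_mm3,2.48,0.51
CA1,Tg,mean_len_um,111,15
CA1,Tg,rdiff_um,5.74,0.54
DG,nonTg,v_mm3,2.05,0.30
DG,nonTg,vol_fraction_pct,4.43,0.68
DG,nonTg,n_cap,69840,37760
DG,nonTg,n_endp,35283,18875
DG,nonTg,nv_per_mm3,35192,20617
DG,nonTg,nvendp_per_mm3,17776,10315
DG,nonTg,l_m,3.40,1.34
DG,nonTg,lv_m_per_mm3,1.70,0.74
DG,nonTg,mean_len_um,53,11
DG,nonTg,rdiff_um,7.28,1.71
DG,Tg,v_mm3,1.98,1.09
DG,Tg,vol_fraction_pct,3.88,1.70
DG,Tg,n_cap,45521,34532
DG,Tg,n_endp,23127,17241
DG,Tg,nv_per_mm3,21255,8197
DG,Tg,nvendp_per_mm3,10887,4164
DG,Tg,l_m,1.72,0.29
DG,Tg,lv_m_per_mm3,1.08,0.49
DG,Tg,mean_len_um,63,48
DG,Tg,rdiff_um,9.31,2.67
PCL,nonTg,v_mm3,5.61,0.60
PCL,nonTg,vol_fraction_pct,12.17,1.78
PCL,nonTg,n_cap,148864,39724
PCL,nonTg,n_endp,400877,254667
PCL,nonTg,nv_per_mm3,27060,8621
PCL,nonTg,nvendp_per_mm3,74552,51663
PCL,nonTg,l_m,9.88,1.51
PCL,nonTg,lv_m_per_mm3,1.78,0.37
PCL,nonTg,mean_len_um,68,11
PCL,nonTg,rdiff_um,6.76,0.69
PCL,Tg,v_mm3,4.67,1.68
PCL,Tg,vol_fraction_pct,9.31,2.41
PCL,Tg,n_cap,163946,70666
PCL,Tg,n_endp,88036,35259
PCL,Tg,nv_per_mm3,35911,13883
PCL,Tg,nvendp_per_mm3,19393,6857
PCL,Tg,l_m,9.30,3.36
PCL,Tg,lv_m_per_mm3,2.07,0.67
PCL,Tg,mean_len_um,60,11
PCL,Tg,rdiff_um,6.39,0.96
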