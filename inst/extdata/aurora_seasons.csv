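year,location,x_eff_temp_sum,w_rain_sum,et0_july_mean,alpha_calc_ref_pct,alpha_assay_pct
2001,Gregurovec,1698.4,393.7,4.26,10.9,11.6
2002,Gregurovec,1932.1,425.8,4.20,11.3,11.1
2003,Gregurovec,1994.4,175.2,5.50,2.5,6.7
2004,Gregurovec,1856.7,398.5,4.28,10.2,10.0
2005,Gregurovec,1920.8,403.3,4.38,10.1,9.7
2006,Gregurovec,1872.1,382.0,4.42,9.2,9.3
2012,Zalec,1766.2,400.4,4.20,10.8,10.2
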