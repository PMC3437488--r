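d_lo_um,d_hi_um,group,E_million_per_h_person,pct_of_total,note
0.4,1.1,skin_hair_nostrils,0.06,13,
1.1,2.1,skin_hair_nostrils,0.14,7.3,
2.1,3.3,skin_hair_nostrils,NA,NA,failed_pcr
3.3,4.7,skin_hair_nostrils,2.7,18,
4.7,9,skin_hair_nostrils,2.0,15,
9,20,skin_hair_nostrils,0.53,32,
0.4,1.1,oral_cavity,NA,NA,not_detected
1.1,2.1,oral_cavity,0.03,1.8,
2.1,3.3,oral_cavity,NA,NA,failed_pcr
3.3,4.7,oral_cavity,NA,NA,not_detected
4.7,9,oral_cavity,0.5,4,
9,20,oral_cavity,NA,NA,not_detected
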