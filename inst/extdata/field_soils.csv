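sample_id,ph,temp_k,time_years,corg_pct,total_cu_mg_kg,e_add_obs
Hygum1,5.43,288.0,78,2.58,41.1,0.36
Hygum2,5.53,288.0,78,2.58,75.3,0.40
Hygum3,5.63,288.0,78,2.58,201.1,0.47
Hygum4,5.49,288.0,78,2.58,298.2,0.54
Hygum5,5.62,288.0,78,2.58,304.5,0.54
Hygum6,5.48,288.0,78,2.58,337.1,0.50
Hygum7,5.42,288.0,78,2.58,406.4,0.55
Hygum8,5.19,288.0,78,2.58,463.6,0.57
Woburn1,6.36,282.5,8,1.5,45.6,0.59
Woburn2,6.36,282.5,8,1.5,89.8,0.56
Woburn3,6.36,282.5,8,1.5,115.6,0.60
WagningenA1,3.86,282.5,22,1.5,27.5,0.38
WagningenA2,3.87,282.5,22,1.5,45.4,0.47
WagningenA3,3.98,282.5,22,1.5,44.9,0.46
WagningenD1,5.43,282.5,22,1.5,46.0,0.56
WagningenD2,5.14,282.5,22,1.5,55.5,0.60
WagningenD3,5.48,282.5,22,1.5,71.2,0.53
Italy1,7.14,288.5,40,3.1,60.2,0.29
Italy2,7.14,288.5,40,3.1,121.8,0.31
Hungary1,7.30,283.5,13,2.7,40.5,0.28
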