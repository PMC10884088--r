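statistic,age,p_sys,p_dias,hr,co,strain_ann,strain_sinus,strain_stj,orifice_area,ji,e_mpa
mean,83,129.4,61.2,70.6,3977.9,4.6,4.0,4.5,114.0,87.0,5.6
sd,4,18.3,11.2,10.9,1046.3,2.4,2.7,2.2,23.1,2.2,1.3
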