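id,age,sex,p_sys,p_dias,hr,co,strain_ann,strain_sinus,strain_stj,orifice_area,ji,e_mpa
1,79,M,162.0,48.0,92.0,5336.0,3.4,1.4,4.8,140.2,91.5,6.1
2,90,F,140.0,75.0,87.0,4611.0,3.6,0.7,5.3,86.5,86.9,6.2
3,85,F,160.0,90.0,65.0,3174.0,1.8,3.1,0.3,119.0,90.1,6.2
4,83,F,143.0,60.0,67.0,4690.0,5.8,5.2,1.9,87.8,83.7,6.3
5,86,F,107.0,59.0,91.0,5005.0,7.4,8.6,3.7,105.4,85.2,5.2
6,85,F,150.0,52.0,61.0,3416.0,8.0,3.6,6.8,70.8,86.9,3.8
7,85,F,138.0,78.0,74.0,2442.0,2.0,1.8,1.8,119.8,88.6,6.2
8,89,M,120.0,58.0,63.0,3591.0,1.7,1.8,4.3,112.8,86.7,6.2
9,91,F,138.0,55.0,69.0,2415.0,4.6,8.5,6.1,108.4,84.2,7.7
10,83,F,110.0,52.0,65.0,4485.0,1.9,0.4,1.8,102.2,85.3,7.4
11,75,M,100.0,55.0,64.0,4575.0,4.3,1.6,7.2,104.3,86.7,6.2
12,85,F,151.0,54.0,67.0,2881.0,9.1,3.6,4.0,97.8,85.9,3.4
13,86,F,119.0,58.0,62.0,3162.0,3.5,3.7,4.2,109.4,86.5,5.9
14,84,M,123.0,78.0,68.0,3808.0,3.2,4.1,4.4,125.7,90.3,5.0
15,79,F,126.0,60.0,61.0,3104.0,8.2,8.5,7.9,165.2,84.9,3.9
16,75,M,128.0,47.0,62.0,3968.0,1.8,2.1,1.8,140.8,85.7,7.5
17,82,M,113.0,64.0,81.0,6399.0,7.4,7.7,8.2,100.8,86.9,4.9
18,78,M,136.0,67.0,60.0,5100.0,3.5,2.8,3.1,138.6,89.9,5.9
19,82,M,105.0,55.0,65.0,3185.0,6.2,6.1,6.4,145.2,88.5,4.9
20,85,F,118.0,58.0,88.0,4210.0,4.8,5.1,5.2,98.5,85.1,3.6
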