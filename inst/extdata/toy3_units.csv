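unit_id,name,lat,lon,population,beds,designated_region,micro_region
A,Alfa,-21.20,-47.90,10000,20,D1,M1
B,Beta,-21.05,-47.75,5000,120,D1,M1
C,Gama,-20.90,-47.60,4000,30,D1,M2
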