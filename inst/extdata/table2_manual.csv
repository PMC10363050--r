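patient,bone_phys1,bone_phys2,bone_total,vas_phys1,vas_phys2,vas_total
1,0.7,1.0,0.9,8.3,7.3,7.8
2,0.0,0.3,0.2,4.2,3.9,4.1
3,0.3,0.5,0.4,18.0,17.0,17.5
4,0.9,0.2,0.1,9.9,8.3,9.1
5,0.0,0.3,0.2,14.0,15.0,14.5
6,0.3,0.1,0.2,5.6,5.6,5.6
7,0.5,0.1,0.3,3.3,0.6,2.0
8,0.1,0.2,0.2,2.0,2.1,2.1
9,0.1,0.3,0.2,0.5,0.9,0.7
10,1.0,0.8,0.9,2.2,2.5,2.4
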