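patient,phase,pair,m_bone,m_vas,manual_adjustment
1,global,L2-L3,2.0,17.0,FALSE
1,local,L4-L5,0.5,11.0,FALSE
2,global,L4-L5,3.0,7.0,FALSE
2,local,L2-L3,0.0,5.0,FALSE
3,global,L4-L5,1.8,16.0,FALSE
3,local,L4-L5,0.0,13.0,FALSE
4,global,L4-L5,2.5,5.0,FALSE
4,local,L4-L5,0.0,4.0,FALSE
5,global,L2-L3,1.5,9.0,TRUE
5,local,L2-L3,1.5,9.0,TRUE
6,global,T12-L1,2.5,3.0,FALSE
6,local,L2-L3,0.5,2.0,FALSE
7,global,L2-L3,1.3,1.0,FALSE
7,local,L4-L5,1.0,1.0,FALSE
8,global,T12-L1,0.0,4.0,TRUE
8,local,T12-L1,0.0,4.0,TRUE
9,global,L4-L5,0.8,11.0,FALSE
9,local,L2-L3,0.0,6.0,FALSE
10,global,T12-L1,1.0,17.0,TRUE
10,local,L4-L5,1.0,14.0,TRUE
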