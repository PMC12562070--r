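Trajectories,P01,STA
120
,,C7,,,L1,,,L3,,,L5,,,S1,,,RPSI,,,LPSI,,
Frame,Sub Frame,X,Y,Z,X,Y,Z,X,Y,Z,X,Y,Z,X,Y,Z,X,Y,Z,X,Y,Z
,,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,mm,m,m,m,mm,mm,mm
1,0,-132.5,0.2,1475.3,-95.1,0.1,1310.4,-108.9,-0.3,1245.2,-95.0,0.4,1180.1,-91.2,0.0,1146.8,-0.0701,-0.0450,1.0000,-70.3,44.8,999.8
2,0,-132.4,0.1,1475.2,-95.2,0.2,1310.2,,,,-95.1,0.3,1180.0,-91.1,0.1,1146.9,-0.0700,-0.0451,1.0001,-70.2,44.9,999.9
3,0,-132.6,0.3,1475.4,-95.0,0.0,1310.5,-108.8,-0.2,1245.3,-94.9,0.5,1180.2,-91.3,-0.1,1146.7,-0.0702,-0.0449,0.9999,-70.4,44.7,999.7
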