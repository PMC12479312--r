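feature,position,nts,weight
Intercept,,,0.59763615
GC_low,,,-0.2026259
GC_high,,,-0.1665878
G02,2,G,-0.2753771
A03,3,A,-0.3238875
C03,3,C,0.17212887
C04,4,C,-0.1006662
C05,5,C,-0.2018029
G05,5,G,0.24595663
A06,6,A,0.03644004
C06,6,C,0.09837684
C07,7,C,-0.7411813
G07,7,G,-0.3932644
A12,12,A,-0.466099
A15,15,A,0.08537695
C15,15,C,-0.013814
A16,16,A,0.27262051
C16,16,C,-0.1190226
T16,16,T,-0.2859442
A17,17,A,0.09745459
G17,17,G,-0.1755462
C18,18,C,-0.3457955
G18,18,G,-0.6780964
A19,19,A,0.22508903
C19,19,C,-0.5077941
G20,20,G,-0.4173736
T20,20,T,-0.054307
G21,21,G,0.37989937
T21,21,T,-0.0907126
C22,22,C,0.05782332
T22,22,T,-0.5305673
T23,23,T,-0.8770074
C24,24,C,-0.8762358
G24,24,G,0.27891626
T24,24,T,-0.4031022
A25,25,A,-0.0773007
C25,25,C,0.28793562
T25,25,T,-0.2216372
G28,28,G,-0.6890167
T28,28,T,0.11787758
C29,29,C,-0.1604453
G30,30,G,0.38634258
GT02,2,GT,-0.6257787
GC05,5,GC,0.30004332
AA06,6,AA,-0.8348362
TA06,6,TA,0.76062777
GG07,7,GG,-0.4908167
GG12,12,GG,-1.5169074
TA12,12,TA,0.7092612
TC12,12,TC,0.49629861
TT12,12,TT,-0.5868739
GG13,13,GG,-0.3345637
GA14,14,GA,0.76384993
GC14,14,GC,-0.5370252
TG17,17,TG,-0.7981461
GG19,19,GG,-0.6668087
TC19,19,TC,0.35318325
CC20,20,CC,0.74807209
TG20,20,TG,-0.3672668
AC21,21,AC,0.56820913
CG21,21,CG,0.32907207
GA21,21,GA,-0.8364568
GG21,21,GG,-0.7822076
TC22,22,TC,-1.029693
CG23,23,CG,0.85619782
CT23,23,CT,-0.4632077
AA24,24,AA,-0.5794924
AG24,24,AG,0.64907554
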