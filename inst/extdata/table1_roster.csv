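id,sex,matriline,n_relatives,social_rank,ds
YL,male,,0,1,205.24
YXK,male,Y,6,2,176.94
ZB,male,,0,3,137.17
YXX,female,Y,6,4,125.5
YH,female,Y,6,5,82.63
DB,male,,0,6,81.58
NM,male,,0,7,71.93
TQ,male,,0,8,61.68
WM,male,,0,9,39.85
YCY,female,Y,6,10,28.62
YXY,female,Y,6,11,25.08
YCH,female,,0,12,2.04
TXH,female,T,6,13,-14.6
YCL,female,Y,6,14,-23.26
DZ,male,,0,15,-24.75
TQS,male,T,6,16,-29.32
BHZ,male,,0,17,-41.48
TH,female,T,6,18,-48
TXX,female,T,6,19,-68.08
TQL,female,T,6,20,-76.17
THY,female,TH,2,21,-85.9
TQY,female,T,6,22,-93.89
QT,male,,0,23,-113.9
THX,female,TH,2,24,-138.21
YXM,male,Y,6,25,-145.67
TFH,female,TH,2,26,-150.35
TQG,female,T,6,27,-153.02
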