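target,depth_class,mean_cp,sd_cp,n
rnpB-HL,3m,20.98,2.34,61
rnpB-HL,DCM,22.65,2.73,61
rnpB-HL,DCM+40,26.17,2.57,60
rbcL-HL,3m,21.09,2.35,61
rbcL-HL,DCM,24.05,2.8,61
rbcL-HL,DCM+40,28.71,2.33,60
psbA-HL,3m,16.87,2.38,61
psbA-HL,DCM,19.85,2.71,61
psbA-HL,DCM+40,23.64,2.31,60
rnpB-LL,3m,26,3.09,61
rnpB-LL,DCM,18.8,1.58,61
rnpB-LL,DCM+40,20.67,2.25,60
rbcL-LL,3m,31.83,3.14,61
rbcL-LL,DCM,23.22,2.63,61
rbcL-LL,DCM+40,24.84,2.72,60
psbA-LL,3m,25.07,3.85,61
psbA-LL,DCM,17.38,2.51,61
psbA-LL,DCM+40,20.02,2.85,60
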