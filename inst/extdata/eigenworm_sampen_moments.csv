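group,label,n,mean,sd
d0.1,N2,109,0.3091,0.2032
d0.1,goa-1,44,0.4239,0.1309
d0.1,unc-1,35,0.4692,0.2278
d0.1,unc-38,45,0.2169,0.1342
d0.1,unc-63,25,0.1723,0.1003
d0.2,N2,109,0.1845,0.1326
d0.2,goa-1,44,0.2666,0.0916
d0.2,unc-1,35,0.2423,0.1306
d0.2,unc-38,45,0.1020,0.0548
d0.2,unc-63,25,0.0753,0.0419
d0.3,N2,109,0.1261,0.0833
d0.3,goa-1,44,0.2039,0.0759
d0.3,unc-1,35,0.1485,0.0916
d0.3,unc-38,45,0.0612,0.0281
d0.3,unc-63,25,0.0431,0.0233
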