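group,label,n,mean,sd
c3,N2,109,5.4800,0.8322
c3,goa-1,44,5.5729,0.8274
c3,unc-1,35,5.5454,0.6354
c3,unc-38,45,5.5037,0.7124
c3,unc-63,25,5.7802,1.0175
c5,N2,109,5.2741,0.4828
c5,goa-1,44,5.4309,0.5718
c5,unc-1,35,5.4701,0.7688
c5,unc-38,45,5.3694,0.5343
c5,unc-63,25,5.6012,0.8915
c7,N2,109,5.2862,0.4946
c7,goa-1,44,5.5029,0.6823
c7,unc-1,35,5.2543,0.5388
c7,unc-38,45,5.3543,0.4108
c7,unc-63,25,5.3377,0.3878
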