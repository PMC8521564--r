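group,label,n,mean,sd
LSI,HC,16,1.0265,0.2934
LSI,PD,15,0.8603,0.2849
LSI,HD,20,1.0914,0.2077
LSI,ALS,13,0.9138,0.2606
RSI,HC,16,0.9627,0.3257
RSI,PD,15,0.8592,0.3037
RSI,HD,20,1.0843,0.2923
RSI,ALS,13,0.9523,0.3480
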