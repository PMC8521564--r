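group,label,n,mean,sd
LSI,HC,16,5.9875,1.0132
LSI,PD,15,6.2174,0.8175
LSI,HD,20,6.4782,0.9651
LSI,ALS,13,6.3764,1.0848
RSI,HC,16,6.3076,1.1803
RSI,PD,15,6.5289,1.2089
RSI,HD,20,6.5297,0.9547
RSI,ALS,13,6.6049,1.0707
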