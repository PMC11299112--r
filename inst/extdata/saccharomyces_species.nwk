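((((((Scer:0.06,Spar:0.06)Anc1:0.04,Smik:0.11)Anc2:0.04,Sjur:0.14)Anc3:0.04,Skud:0.17)Anc4:0.04,Sarb:0.2)Anc5:0.05,(Suva:0.1,Seub:0.1)AncOut:0.15)Root;
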