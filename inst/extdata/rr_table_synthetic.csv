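zone,rr
1,1.030
2,1.045
3,1.060
4,1.080
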