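year,cost
1,900
2,700
3,500
4,400
5,300
6,250
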