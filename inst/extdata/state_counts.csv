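state,count
1,361
2,604
3,83
4,345
5,145
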