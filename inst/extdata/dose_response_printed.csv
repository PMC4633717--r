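dose_uM,fraction,responder,source
2,0.56,A,published_text
28,0.90,A,published_text
75,0.90,A,published_text
0,0.01,B,published_text
2,0.01,B,published_text
10,0.09,B,published_text
28,0.46,B,published_text
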