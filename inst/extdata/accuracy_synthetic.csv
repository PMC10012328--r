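offset,accuracy
0,0.52
90,0.38
180,0.37
270,0.39
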