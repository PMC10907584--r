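group,value
A,31.2
A,28.5
A,35.1
A,30.4
B,27.9
B,26.3
B,29.8
B,25.4
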