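#absorbing: D
"","H","I","D"
"H",0.6,0.3,0.1
"I",0.2,0.5,0.3
"D",0,0,1
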