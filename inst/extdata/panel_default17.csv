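group,param_index
Ang,2
Ang,6
Ang,9
Ang,12
Ang,13
Ang,40
Len,1
Len,14
Len,15
Len,3
Len,5
Len,32
Vol,10
Vol,11
Vol,31
Vol,38
Vol,39
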