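category,control,treated
16-20,2,0
21-25,9,7
26-30,37,26
31-35,50,29
36-40,38,19
41-45,4,1
46-50,3,0
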