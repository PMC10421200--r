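2
box="200.000000 200.000000 200.000000" periodic="FFF"
SURF   100.00000000   100.00000000     0.00000000
X      100.00000000   100.00000000     8.00000000
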