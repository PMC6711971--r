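ATP1A4
WDR66
TEKT2
TEKT5
DRC7
CFAP44
DDX4
DNAJA1
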