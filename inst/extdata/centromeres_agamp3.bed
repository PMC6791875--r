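2L	0	10000000	centromeric
2R	50000000	61300000	centromeric
3L	0	10000000	centromeric
3R	40000000	53100000	centromeric
X	15000000	20200000	centromeric
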