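participant,aq
A1,30
A2,28
A3,30
A4,21
A5,38
A6,33
A7,35
A8,34
A9,38
A10,36
A11,35
A12,30
A13,10
A14,32
A15,22
A16,37
A17,38
A18,23
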