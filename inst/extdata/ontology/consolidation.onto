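MODULE	consolidation
IMPORT	core
IMPORT	medical
IMPORT	socio-environnemental
IMPORT	coordination
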