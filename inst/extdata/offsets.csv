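kinase,offset,basis
EGFR,24,mature numbering Y845 equals alternate numbering Y869
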