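accession	taxid
REF001	13
REF002	14
REF003	23
REF004	31
REF005	40
REF006	15
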