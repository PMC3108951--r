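>mir_a
UGGAAUGUAAAGAAGUAUGUAU
>mir_b
UUGUUAUGACCCCGCGACCCCC
>mir_c
AGAAGUGCCAACUUAACGCCAG
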