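>gene01
UACGUUUCCAUUUUGGUGUUAAGUGUUGGAUUAGCUAUCCCACACAUUAAGGUUUUAUGAAGUACGUCAUAACACCAUUUAUCAUGUUAAUUUACGGCAUCUGCAUAUUAUAAUUUCCCAUCAAGAGGGGACCUUUGGUUUAGAGCUUUUGCCCUCAAGAUAGAUUAGAUAAUCGUCGCUGUCGAAUUCAGCUAGCCCUCCUUCCGGUAAGUCUAUCCCA
>gene02
GGACUUUAACUCUCCUGCCAGUUCAUGAUGUUAUGAGCGAUACACGAAUUUCACCUAUAUCACUGGACUCCAACACACUUCCAUGUGUUAGUAAGCAGUGUACAAAUAGAUAGAUUAAGUUUCAUAUGGCAAUGAAGCAUCUCCGAUCGCGCAUGUUGUGUUACUUCUAAUAACGAUUAUCAAGACUAUCUCUUGGUACGCGGGAUUGUCCAACGAAUAC
>gene03
AUUCAUAAGUGAUGGAAUAUAGUUAACGCUAGAUACUUGCCUGGCCUGGGUCUUGCAGCUGACGUGUGGGCCCUUUAAGAUCCAUUCCCUGGUGAUGUGCAACCAUCGUUGAGCGAAAAAAGAUUAUGUUGUCCUGACCCUCGCUUUGGAAUUUAUAUUAGAAUACUCUGCGAGCAUAAGAACGUUUUGUUGAACAAUUAAGUCAUGGACCUAUAGAGGA
>gene04
UAUUAGGUUGAUUAGGAAUUUAUCCACUAUGUAACAACCAAUAUAUCCAAUAUAUUCUCUGUUAACUGGAAAUGUCCAUAUAGAACUGCAUAACACCAAAUGCUAGGCAGGUCGGAAUAAUUCAUUGGCGUCAGCAUUCGACUGUGGAUAUAUCAAGGCUACGACAGGACCGUCAACAUACAACUUCAAGAAAUUUACAUUGUGUCCGACCAUAGUGAAC
>gene05
CCCUAUUCAAACCCCAAUCCAUACCACAACCAACCGUAGCCGAGCAGAGAACUCUCACUUUCAUCACACGCUGUUUCCGGUCUUACCGCUCUACAACACUUCCAGUUAAACAUACCACGAAGUCAUGUUAUGAACGACUGGCCUUUAUAUGCUGCCUCUGCCAAACCUAUGUUGUCUUCACCCAAGAUAAGAAGCAGGUUCGACCACAUACAUCCUUGAC
>gene06
GAAACUUAGGAAACCUUGGAAAACAUUAGUAGUGGUUUAAUCCUAAUGUUUGCAUUGACCUGUUAAUCGUUCAUAACAUUAAACCGGAGAUAGAUAAUGUUCCCAUUCCCUUCUACCUCAAACUCUCUCGAUCGUUAGUGUCGGUUACAAGGAUUGAGGUCAUAUUGGGAAAGCGGGUACUAUCAACGAUGUACAGAGGUUAACGCUUGAGCCAUUAAUA
>gene07
UUAGUUUUUCGUUAUGCUAAAACAAUGAAAGAUGUCAUAUUGGUGGGGUUAUCUAUUUAUAUUCGUCUUAGCGAGAAAGAUCUUGAUUUAAGGCGAGUUCCCGUACCGCAGUGUAUUAAGAAGCAAAGUACCACAGGCGGGAGGUAUCCGUCAUCCGUAUAUCCAUCGUUUAAUAUCCGUAUUAAAGAGAUACCCCAUUACAAACGGAGCUUUAAUUAUA
>gene08
GCUAAGAAAUUAAAACACUCUAACGUACAUAUCUACUAGUCCACGAGAGCGAAGAGAAAUCACCUUUCCGAUGUGAGGAUUGCAAACAGAGAUUAUCCACCCUUCUAAGUAGCUAUGUCCAUGCGUGUACUAAACCAGAGGCGUUUAUGAUGGUGUACGAAAAUGUACUGGUACCUAGCGAUAGUAGAACAAACACAAUUCAUAUGGCUCUAUCCAUGUA
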