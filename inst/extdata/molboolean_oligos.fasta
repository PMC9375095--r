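>circle_part_1 mod=phosphate role=circle_part
TTTATCTATATCTGCCACGCTACTTACGTCTCTCGTCTGATGCTCCACCTCATATATAAA
TTGTGTCCACTCGTCTCACTGCTCAACTACCTACCTCAGGAGAAACCTTTACTT
>circle_part_2 mod=phosphate role=circle_part
CGAGGTGCTTTTAGCACCTCGAAGTAAAGCTATCCACTGTCACCAACTACTAGATAAACG
TCACACTTTTCGTGTGACG
>arm_A mod=aldehyde role=arm
AAAAAAAAACTCCTGAGGTAGGTAGTTGAGCAGCATCCGCACTTATAGCTGCAGTGAGAC
GAGTGGACAC
>arm_B mod=aldehyde role=arm
AAAAAAAAATGAGGTGGAGCATCAGACGGTAATTAACCCGCCCCGTACGAGAGACGTAAG
TAGCGTGGCA
>tag_A mod=phosphate role=tag
CTGCAGCTATAAGTGCGGATG
>tag_B mod=phosphate role=tag
CGTACGGGGCGGGTTAATTAC
>detection_A mod=fluorophore role=detection tail=UUU
CTGCAGCTATAAGTGCGGATG
>detection_B mod=fluorophore role=detection tail=UUU
CGTACGGGGCGGGTTAATTAC
>padlock_A mod=phosphate role=padlock
AGTGCGGATGCTGCTCAACTACCTACACCTCGAAGTAAAGCTATCCACTGTCACCAACTA
CTAGATAAACGTCACTCCACTCGTCTCACTGCAGCTATA
>padlock_B mod=phosphate role=padlock
GGTTAATTACCGTCTGATGCTCCACACCTCGAAGTAAAGCTATCCACTGTCACCAACTAC
TAGATAAACGTCACCTACTTACGTCTCTCGTACGGGGCG
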