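Ralstonia
Sphingomonas
Pseudomonas
Burkholderia
Bradyrhizobium
Methylobacterium
Delftia
Acinetobacter
Comamonas
Stenotrophomonas
Herbaspirillum
Phyllobacterium
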