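# canonical residues plus the ambiguity/rare codes tolerated on input
.aa_canonical <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.aa_tolerated <- c(.aa_canonical, "X", "B", "Z", "U")
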