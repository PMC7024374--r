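>turgencin_A mature 36-residue peptide, C-terminally amidated
GPKTKAACKMACKLATCGKKPGGWKCKLCELGCDAV
>turgencin_B mature 35-residue peptide, C-terminally amidated
GIKEMLCNMACAQTVCKKSGGPLCDTCQAACKALG
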