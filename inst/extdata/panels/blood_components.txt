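# Abundant blood-component proteins: albumin, hemoglobin subunits,
# red-blood-cell membrane/cytosol proteins, platelet proteins.
ALB
HBA1
HBB
HBD
SLC4A1  # RBC band 3
ANK1
SPTA1
SPTB
EPB42
CA1
CA2
BLVRB
GP1BA
ITGA2B
ITGB3
PF4
THBS1
VWF
PPBP
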