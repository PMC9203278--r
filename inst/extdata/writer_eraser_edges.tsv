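modifier	mark	relation
EZH2	H3:K27:me3	writes
EZH2	H3:K27:me2	writes
EZH1	H3:K27:me3	writes
KDM6A	H3:K27:me3	erases
KDM6B	H3:K27:me3	erases
DOT1L	H3:K79:me1	writes
DOT1L	H3:K79:me2	writes
KMT2A	H3:K4:me1	writes
KMT2D	H3:K4:me1	writes
SETD1A	H3:K4:me3	writes
KDM5B	H3:K4:me3	erases
KDM1A	H3:K4:me1	erases
NSD1	H3:K36:me2	writes
NSD2	H3:K36:me2	writes
SETD2	H3:K36:me3	writes
KDM2A	H3:K36:me2	erases
KDM4A	H3:K36:me3	erases
SUV39H1	H3:K9:me3	writes
SETDB1	H3:K9:me3	writes
EHMT2	H3:K9:me2	writes
KDM3A	H3:K9:me2	erases
KDM4C	H3:K9:me3	erases
EP300	H3:K27:ac	writes
CREBBP	H3:K27:ac	writes
KAT2A	H3:K9:ac	writes
HDAC1	H3:K27:ac	erases
HDAC2	H3:K9:ac	erases
KAT5	H4:K16:ac	writes
SIRT1	H4:K16:ac	erases
SUV420H1	H4:K20:me2	writes
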