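# Candidate enzyme catalog for double-digest RR-seq design.
# Recognition sites <= 6 bp, methylation-insensitive NEB-HF-style enzymes,
# no duplicate recognition sequences. cut_offset is the 0-based top-strand
# cut position within the recognition sequence.
name	recognition	cut_offset
PstI	CTGCAG	5
ApoI	RAATTY	1
EcoRI	GAATTC	1
MspI	CCGG	1
NsiI	ATGCAT	5
MluCI	AATT	0
BamHI	GGATCC	1
HindIII	AAGCTT	1
SphI	GCATGC	5
NcoI	CCATGG	1
AseI	ATTAAT	2
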