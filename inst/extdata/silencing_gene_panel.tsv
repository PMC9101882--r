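# TE-silencing gene panel quantified by the calibration stage:
# 4 Argonaute-subfamily genes, 6 heterochromatin-formation genes,
# 14 NuRD-complex genes, plus TRIM33 and the actinopterygian KRAB-like.
# Greek letters in HP1 isoform names are transliterated (HP1a = HP1-alpha,
# HP1ba/HP1bb = HP1-beta a/b, HP1g = HP1-gamma).
gene	category
AGO1	argonaute
AGO2	argonaute
AGO3	argonaute
AGO4	argonaute
HP1a	heterochromatin
HP1ba	heterochromatin
HP1bb	heterochromatin
HP1g	heterochromatin
DNMT1	heterochromatin
DNMT3aa	heterochromatin
CHD3	nurd
CHD4a	nurd
CHD4b	nurd
HDAC1	nurd
HDAC2	nurd
MBD2	nurd
MBD3b	nurd
MTA1	nurd
MTA2	nurd
MTA3	nurd
GATAD2ab	nurd
GATAD2b	nurd
RBBP4	nurd
RBBP7	nurd
TRIM33	recruiter
KRAB-like	recruiter
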