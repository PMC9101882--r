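# RepeatMasker class/family vocabulary -> TE class mapping.
# `prefix` is matched (first match wins, file order) against the part of the
# class/family string before the first "/"; e.g. "LINE/L2" matches on "LINE".
# RC (rolling-circle/Helitron) elements count as DNA transposons; Retroposon
# covers non-LTR retroelements that are neither LINEs nor SINEs. NonTE marks
# repeat categories that are not transposable elements and are discarded.
prefix	te_class
SINE	SINE
LINE	LINE
LTR	LTR
DNA	DNA
RC	DNA
Retroposon	Retro
Unknown	Unclear
Unspecified	Unclear
Simple_repeat	NonTE
Low_complexity	NonTE
Satellite	NonTE
rRNA	NonTE
tRNA	NonTE
snRNA	NonTE
scRNA	NonTE
srpRNA	NonTE
ARTEFACT	NonTE
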