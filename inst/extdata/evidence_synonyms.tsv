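# Evidence-label synonym table for validated miRNA-target interactions.
# Matching is case-insensitive after trimming; labels are mapped to their
# canonical form before whitelist comparison.
label	canonical
western blotting	western blot
western-blot	western blot
wb	western blot
rt-qpcr	qrt-pcr
qpcr	qrt-pcr
quantitative rt-pcr	qrt-pcr
reverse transcription quantitative pcr	qrt-pcr
real-time rt-pcr	qrt-pcr
luciferase assay	luciferase reporter assay
luciferase reporter	luciferase reporter assay
reporter assay	luciferase reporter assay
reporter assay;luciferase	luciferase reporter assay
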