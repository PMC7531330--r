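# Human-plant miRNA seed-comparison regression fixture: 20 human miRNAs
# paired with 7 crop-plant miRNAs by perfect same-frame seed identity.
# Transcription corrections applied to the printed source table:
#   "lisa-miR-34c-5p"      -> "hsa-miR-34c-5p"   (OCR: lisa -> hsa)
#   "lisa-miR-593-5p"      -> "hsa-miR-593-5p"   (OCR: lisa -> hsa)
#   "hsa-miR-450a-l-3p"    -> "hsa-miR-450a-1-3p" (OCR: letter l -> digit 1)
#   "type _2_7, typ e_3_8" -> frames F2_7,F3_8    (stray spaces removed)
# The gma-miR5677 rows print the concatenation of the 3-8 and 2-7 seeds
# (UGGUCC+UUGGUC); they are stored per frame here. Frame labels are kept as
# printed: note the classifier itself reports simultaneous 2-7 and 3-8
# identity as the subsuming F2_8.
human_id	plant_id	frames	seed_2_7	seed_2_8	seed_3_8
hsa-miR-1254	gma-miR160	F2_7	GCCUGG
hsa-miR-661	gma-miR160	F2_7	GCCUGG
hsa-miR-450a-1-3p	gma-miR4351	F2_8		UUGGGAA
hsa-miR-483-5p	gma-miR4368	F2_7	AGACGG
hsa-miR-34a-5p	gma-miR4995	F2_8		GGCAGUG
hsa-miR-34c-5p	gma-miR4995	F2_8		GGCAGUG
hsa-miR-449a	gma-miR4995	F2_8		GGCAGUG
hsa-miR-449b-5p	gma-miR4995	F2_8		GGCAGUG
hsa-miR-133a-3p	gma-miR5677	F2_7,F3_8	UUGGUC		UGGUCC
hsa-miR-133b	gma-miR5677	F2_7,F3_8	UUGGUC		UGGUCC
hsa-miR-25-3p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-32-5p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-363-3p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-367-3p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-92a-3p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-92b-3p	mtr-miR5754	F2_8		AUUGCAC
hsa-miR-29a-3p	zma-miR172	F2_8		AGCACCA
hsa-miR-29b-3p	zma-miR172	F2_8		AGCACCA
hsa-miR-29c-3p	zma-miR172	F2_8		AGCACCA
hsa-miR-593-5p	zma-miR172	F2_8		GGCACCA
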