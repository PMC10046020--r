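id	sequence	label
Peptide1	MLPGLALLLLAAWTARA	1
Peptide2	MLPGLALLKLAAWTARA	1
Peptide3	MLPGLALLLLAAWKARA	1
Peptide4	MLPGLALLLLAAWRARA	1
Peptide5	MLKGLALLLLAAWKARA	1
Peptide6	MLPKLALLLLAAWKARA	1
Peptide7	MLKHLALLLLAAWKARA	1
Peptide8	MLAKLALLLLAAWKARA	1
Peptide9	MLKKLALLLLAAWKARA	1
Peptide10	MKPGLALLLLAAKKARA	1
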