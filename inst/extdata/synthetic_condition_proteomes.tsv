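search	condition	protein
tryptic	PMI1	ALBU
tryptic	PMI1	THRB
tryptic	PMI1	FETUA
tryptic	PMI1	HBA
tryptic	PMI1	HBB
tryptic	PMI1	CO1A1
tryptic	PMI1	CO1A2
tryptic	PMI1	K2C1
tryptic	PMI1	K2C4
tryptic	PMI1	K1C10
tryptic	PMI1	K1C13
tryptic	PMI1	SEMG1
tryptic	PMI1	S10AB
tryptic	PMI1	S10A9
tryptic	PMI15C	ALBU
tryptic	PMI15C	THRB
tryptic	PMI15C	FETUA
tryptic	PMI15C	CO1A1
tryptic	PMI15C	CO1A2
tryptic	PMI15C	CO3A1
tryptic	PMI15C	K2C1
tryptic	PMI15C	K1C13
tryptic	PMI15T	THRB
tryptic	PMI15T	CO1A1
tryptic	PMI15T	CO1A2
tryptic	PMI15T	CO3A1
tryptic	PMI15T	PGS1
tryptic	PMI20C	ALBU
tryptic	PMI20C	THRB
tryptic	PMI20C	FETUA
tryptic	PMI20C	CO1A1
tryptic	PMI20C	CO1A2
tryptic	PMI20C	CO3A1
tryptic	PMI20C	K2C4
tryptic	PMI20C	K1C10
tryptic	PMI20C	SEMG1
tryptic	PMI20T	THRB
tryptic	PMI20T	CO1A1
tryptic	PMI20T	CO1A2
tryptic	PMI20T	CO3A1
tryptic	PMI20T	PGS1
tryptic	PMI20T	K1C13
semitryptic	PMI1	ALBU
semitryptic	PMI1	FETUA
semitryptic	PMI1	HBA
semitryptic	PMI1	HBB
semitryptic	PMI1	CO1A1
semitryptic	PMI1	CO1A2
semitryptic	PMI1	K2C1
semitryptic	PMI1	K2C4
semitryptic	PMI1	K1C10
semitryptic	PMI1	K1C13
semitryptic	PMI1	SEMG1
semitryptic	PMI1	S10AB
semitryptic	PMI1	S10A9
semitryptic	PMI1	H10
semitryptic	PMI1	H12
semitryptic	PMI1	H14
semitryptic	PMI1	G3P
semitryptic	PMI1	S10A8
semitryptic	PMI15C	ALBU
semitryptic	PMI15C	FETUA
semitryptic	PMI15C	THRB
semitryptic	PMI15C	CO1A1
semitryptic	PMI15C	CO1A2
semitryptic	PMI15C	CO3A1
semitryptic	PMI15C	K2C1
semitryptic	PMI15C	K1C10
semitryptic	PMI15C	K1C13
semitryptic	PMI15C	S10A8
semitryptic	PMI15C	SEMG1
semitryptic	PMI15T	THRB
semitryptic	PMI15T	CO1A1
semitryptic	PMI15T	CO1A2
semitryptic	PMI15T	CO3A1
semitryptic	PMI15T	PGS1
semitryptic	PMI15T	K1C13
semitryptic	PMI15T	FETUA
semitryptic	PMI20C	ALBU
semitryptic	PMI20C	FETUA
semitryptic	PMI20C	THRB
semitryptic	PMI20C	CO1A1
semitryptic	PMI20C	CO1A2
semitryptic	PMI20C	CO3A1
semitryptic	PMI20C	K2C4
semitryptic	PMI20C	K1C10
semitryptic	PMI20C	K1C13
semitryptic	PMI20C	SEMG1
semitryptic	PMI20C	S10A8
semitryptic	PMI20T	CO1A1
semitryptic	PMI20T	CO3A1
semitryptic	PMI20T	PGS1
semitryptic	PMI20T	K1C13
semitryptic	PMI20T	K2C1
semitryptic	PMI20T	THRB
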