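isoform_id	receptor	variant
iso.NKp44.1	NKP44	NKP44_1
iso.NKp44.2	NKP44	NKP44_2
iso.NKp44.3	NKP44	NKP44_3
iso.NKp30.a	NKP30	NKP30_A
iso.NKp30.b	NKP30	NKP30_B
iso.NKp30.c	NKP30	NKP30_C
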