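# supporting-read counts per repeat pair (published table, used as input)
pair	class	length	n_reference	n_alternative
Repeat-1a_b	IR	8989	104	100
Repeat-2a_b	DR	1467	174	613
Repeat-3a_b	IR	564	822	19
Repeat-4a_b	IR	317	1095	16
Repeat-5a_c	IR	188	553	8
Repeat-5b_c	IR	188	589	5
Repeat-6a_b	DR	161	1055	5
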