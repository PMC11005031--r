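# direct repeats in the E. grandis mitogenome homologous to the large IR
name	length
DR-1	1148
DR-2	366
DR-3	4210
DR-4	206
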