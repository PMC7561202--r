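accession,declared_name
ACC01,Variety 01
ACC02,Variety 02
ACC03,Variety 03
ACC04,Variety 04
ACC05,Variety 05
ACC06,Variety 06
ACC07,Variety 07
ACC08,Variety 08
ACC09,Variety 10
ACC10,Variety 09
ACC11,Variety 11
ACC12,Variety 13
ACC13,Variety 14
ACC14,Variety 15
ACC15,Variety 16
ACC16,Variety 17
ACC17,Variety 01
ACC18,Garnacha do Sul
ACC19,Variety 18
ACC20,Variety 19
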