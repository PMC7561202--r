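prime_name,source,VVS2,VVMD5,VVMD7,VVMD25,VVMD27,VrZAG62,VrZAG79
Variety 01,synthetic-panel,154/156,192/200,212/222,246/248,270/280,314/314,342/346
Variety 02,synthetic-panel,152/166,186/192,212/226,242/260,280/292,308/314,334/350
Variety 03,synthetic-panel,158/168,182/182,214/220,242/244,272/282,322/322,332/344
Variety 04,synthetic-panel,152/168,182/194,224/226,248/260,272/290,308/312,340/346
Variety 05,synthetic-panel,168/170,184/184,216/220,240/240,286/290,304/312,348/352
Variety 06,synthetic-panel,158/164,180/184,216/226,240/250,288/290,300/316,332/342
Variety 07,synthetic-panel,152/172,188/190,212/228,240/262,278/280,300/322,330/350
Variety 08,synthetic-panel,166/168,184/192,230/232,244/258,272/284,304/308,330/352
Variety 09,synthetic-panel,152/156,180/188,218/222,260/262,270/276,316/318,342/344
Variety 10,synthetic-panel,168/170,192/198,214/230,252/258,272/292,306/318,336/344
Variety 11,synthetic-panel,160/160,186/202,210/226,246/260,280/292,318/320,334/352
Variety 12,synthetic-panel,166/166,188/190,222/232,252/262,276/290,306/312,340/346
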