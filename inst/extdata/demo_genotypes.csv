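accession,VVS2,VVMD5,VVMD7,VVMD25,VVMD27,VrZAG62,VrZAG79
ACC01,154/156,192/200,212/222,246/248,270/280,314/314,342/346
ACC02,152/166,186/192,212/226,242/260,280/292,308/314,334/350
ACC03,158/168,182/182,214/220,242/244,272/282,322/322,332/344
ACC04,152/168,182/194,224/226,248/260,272/290,308/312,340/346
ACC05,168/170,184/184,216/220,240/240,286/290,304/312,348/352
ACC06,158/164,180/184,216/226,240/250,288/290,300/316,332/342
ACC07,152/172,188/190,212/228,240/262,278/280,300/322,330/350
ACC08,166/168,184/192,230/232,244/258,272/284,304/308,330/352
ACC09,152/156,180/188,218/222,260/262,270/276,316/318,342/344
ACC10,168/170,192/198,214/230,252/258,272/292,306/318,336/344
ACC11,160/162,186/204,210/228,246/262,280/294,318/322,334/354
ACC12,158/172,184/196,222/228,242/258,292/292,300/308,348/350
ACC13,166/168,194/196,226/232,248/252,280/292,306/316,336/342
ACC14,156/170,182/194,220/232,240/246,288/288,306/320,338/338
ACC15,166/170,182/196,232/232,242/256,284/290,306/316,332/346
ACC16,158/162,184/196,212/224,248/258,272/284,314/320,338/348
ACC17,154/156,192/200,212/222,246/248,270/280,314/314,342/346
ACC18,152/166,186/192,212/226,242/260,280/292,308/314,334/350
ACC19,156/166,194/198,220/226,246/248,274/290,300/318,346/346
ACC20,156/168,186/186,222/222,242/244,280/280,306/320,338/340
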