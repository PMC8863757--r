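participant,group,trial,start_ms,duration_ms,x,y
S01,NOV BC,1,0,383,472,452
S01,NOV BC,1,442,147,906,780
S01,NOV BC,1,639,121,970,396
S01,NOV BC,1,784,207,477,394
S01,NOV BC,1,1014,199,906,863
S01,NOV BC,1,1260,219,446,423
S01,NOV BC,1,1518,260,990,770
S01,NOV BC,1,1800,253,948,395
S01,NOV BC,1,2103,241,462,449
S01,NOV BC,1,2402,158,951,397
S01,NOV BC,1,2581,244,413,400
S01,NOV BC,1,2847,380,107,106
S01,NOV BC,1,3263,174,455,441
S01,NOV BC,1,3477,319,932,828
S01,NOV BC,1,3854,333,946,400
S01,NOV BC,2,0,272,434,507
S01,NOV BC,2,327,374,971,735
S01,NOV BC,2,759,266,1032,413
S01,NOV BC,2,1075,350,494,425
S01,NOV BC,2,1484,222,979,354
S01,NOV BC,2,1743,277,433,459
S01,NOV BC,2,2041,177,938,361
S01,NOV BC,2,2257,383,487,511
S01,NOV BC,2,2666,148,928,823
S01,NOV BC,2,2839,372,988,435
S01,NOV BC,2,3231,315,450,452
S01,NOV BC,2,3569,146,920,426
S01,NOV BC,2,3759,412,476,415
S01,NOV BC,2,4231,292,972,389
S01,NOV BC,2,4562,283,425,444
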