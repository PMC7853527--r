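"wavelength","value"
400,0.00935952474522361
401,0.00990653198859279
402,0.0104743063006157
403,0.011062328774512
404,0.0116699521456576
405,0.0122963975631949
406,0.012940752281179
407,0.0136019683482016
408,0.0142788623674025
409,0.0149701163903514
410,0.0156742799985027
411,0.0163897736148577
412,0.0171148930762066
413,0.0178478154829823
414,0.0185866063294786
415,0.0193292279021377
416,0.0200735489179737
417,0.0208173553591769
418,0.021558362443765
419,0.022294227656036
420,0.0230225647447837
421,0.0237409585820102
422,0.0244469807604573
423,0.0251382057949293
424,0.0258122277803405
425,0.0264666773489065
426,0.0270992387601364
427,0.0277076669504556
428,0.02828980436456
429,0.0288435973881219
430,0.0293671122013244
431,0.0298585498749806
432,0.0303162605357205
433,0.0307387564338998
434,0.0311247237574577
435,0.0314730330468381
436,0.031782748080167
437,0.0320531331139908
438,0.0322836583828168
439,0.0324740037802468
440,0.0326240606653711
441,0.0327339317600341
442,0.0328039291252666
443,0.032834570228286
444,0.0328265721346695
445,0.0327808438832491
446,0.0326984771236383
447,0.03258073511774
448,0.0324290402267803
449,0.0322449600240669
450,0.0320301921905026
451,0.0317865483646374
452,0.0315159371315075
453,0.031220346344489
454,0.0309018249817595
455,0.0305624647435927
456,0.0302043815985617
457,0.0298296974857721
458,0.02944052237652
459,0.0290389368923331
460,0.0286269756673327
461,0.0282066116313864
462,0.0277797413768073
463,0.0273481717556101
464,0.0269136078368079
465,0.0264776423342096
466,0.0260417465949372
467,0.02560726321775
468,0.0251754003485462
469,0.0247472276784357
470,0.0243236741478722
471,0.023905527338793
472,0.0234934345158608
473,0.0230879052580136
474,0.0226893156028602
475,0.0222979136092705
476,0.0219138262279916
477,0.0215370673564716
478,0.0211675469424248
479,0.0208050809911542
480,0.0204494023243178
481,0.0201001719327479
482,0.0197569907630912
483,0.0194194117774239
484,0.0190869521265301
485,0.0187591052811397
486,0.018435352970965
487,0.0181151767887219
488,0.0177980693252936
489,0.0174835447126118
490,0.0171711484624818
491,0.016860466502265
492,0.0165511333218156
493,0.0162428391601465
494,0.0159353361747295
495,0.0156284435509149
496,0.0153220515234667
497,0.015016124296454
498,0.0147107018615343
499,0.0144059007278392
500,0.0141019135890756
501,0.0137990079649592
502,0.0134975238645879
503,0.0131978705287584
504,0.0129005223164575
505,0.0126060138077868
506,0.0123149342013727
507,0.0120279210888847
508,0.0117456536926385
509,0.0114688456544467
510,0.0111982374649363
511,0.0109345886225609
512,0.0106786696105536
513,0.0104312537782064
514,0.0101931092101861
515,0.0099649906642355
516,0.00974763165363394
517,0.00954173674632332
518,0.00934797414772982
519,0.00916696862912974
520,0.00899929485800297
521,0.00884547118127478
522,0.00870595390673669
523,0.00858113212232674
524,0.00847132308739134
525,0.00837676822459289
526,0.00829762973580299
527,0.00823398786015967
528,0.00818583878748407
529,0.00815309323546015
530,0.00813557569438264
531,0.00813302433887134
532,0.00814509160172908
533,0.00817134540107509
534,0.00821127100800562
535,0.00826427353830759
536,0.00832968104816803
537,0.00840674821037581
538,0.0084946605441952
539,0.00859253916890534
540,0.00869944604794717
541,0.0088143896877111
542,0.00893633125224819
543,0.00906419105261535
544,0.00919685536719587
545,0.00933318354720079
546,0.00947201535968582
547,0.00961217851884981
548,0.00975249635514989
549,0.00989179557091252
550,0.0100289140306722
551,0.010162708534463
552,0.0102920625227446
553,0.0104158936625872
554,0.010533161266167
555,0.0106428734945489
556,0.0107440943021212
557,0.0108359500798909
558,0.0109176359590827
559,0.0109884217400725
560,0.0110476574155348
561,0.0110947782607175
562,0.0111293094678663
563,0.0111508703058947
564,0.0111591777903048
565,0.0111540498519851
566,0.0111354079966984
567,0.0111032794497075
568,0.0110577987819293
569,0.0109992090151557
570,0.0109278622041286
571,0.0108442194925449
572,0.0107488506383477
573,0.0106424330009336
574,0.0105257499792173
575,0.0103996888849261
576,0.0102652382301928
577,0.0101234844026751
578,0.00997560769529621
579,0.00982287765158854
580,0.00966664768187586
581,0.00950834890055971
582,0.00934948313100638
583,0.00919161502242689
584,0.00903636322316562
585,0.00888539055742376
586,0.00874039315806855
587,0.00860308851720169
588,0.00847520242888679
589,0.00835845481508364
590,0.00825454444650517
591,0.0081651325947642
592,0.00809182568062189
593,0.00803615701502907
594,0.00799956776443101
595,0.00798338730877065
596,0.00798881319888515
597,0.00801689095849096
598,0.00806849401349343
599,0.00814430406662294
600,0.00824479226699052
601,0.00837020155063622
602,0.00852053054808566
603,0.00869551946697318
604,0.00889463836069535
605,0.00911707818677019
606,0.00936174504027875
607,0.00962725791793689
608,0.00991195032680931
609,0.0102138759986432
610,0.0105308189068882
611,0.0108603077097351
612,0.0111996346604368
613,0.0115458789376679
614,0.0118959342560323
615,0.0122465405226562
616,0.0125943192130011
617,0.0129358120506623
618,0.013267522495132
619,0.0135859594713876
620,0.0138876827186458
621,0.0141693490952787
622,0.0144277591548335
623,0.0146599033057902
624,0.0148630068858042
625,0.0150345735194053
626,0.0151724261851029
627,0.0152747454909889
628,0.0153401047434175
629,0.0153675014860892
630,0.0153563852805832
631,0.0153066815867874
632,0.0152188116747165
633,0.0150937085495086
634,0.0149328288907828
635,0.0147381609887131
636,0.0145122285964984
637,0.0142580905092541
638,0.0139793355230487
639,0.0136800722294329
640,0.0133649128699577
641,0.0130389502269232
642,0.0127077262815865
643,0.0123771911552177
644,0.0120536506919276
645,0.0117437009781357
646,0.0114541481554589
647,0.0111919121030673
648,0.0109639129680255
649,0.010776940124666
650,0.0106375039508884
651,0.0105516718089753
652,0.0105248907814555
653,0.0105618009896812
654,0.0106660446459342
655,0.0108400772736975
656,0.0110849886767639
657,0.0114003421403527
658,0.0117840409009485
659,0.0122322310297998
660,0.0127392494600522
661,0.0132976248990644
662,0.0138981377909263
663,0.0145299433564937
664,0.0151807591109692
665,0.0158371152579298
666,0.0164846631392855
667,0.0171085336699764
668,0.0176937346109705
669,0.0182255728460552
670,0.0186900857275607
671,0.0190744642163408
672,0.0193674500918631
673,0.0195596900233466
674,0.0196440307825861
675,0.0196157422857809
676,0.0194726583519742
677,0.0192152288780632
678,0.018846481327585
679,0.0183718937564119
680,0.0177991857869965
681,0.0171380377379365
682,0.0163997512907379
683,0.015596867449954
684,0.0147427590040029
685,0.0138512151654964
686,0.0129360355733106
687,0.012010649449681
688,0.0110877735558195
689,0.0101791198535239
690,0.00929516066037355
691,0.00844495579593029
692,0.00763604296435465
693,0.00687438959368341
694,0.00616440171071853
695,0.0055089832900452
696,0.00490963794867533
697,0.00436660389176933
698,0.00387901263543755
699,0.00344506218934612
700,0.00306219599629567
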