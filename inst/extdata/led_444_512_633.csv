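"wavelength","value"
400,0.0012038599948282
401,0.00162843004824121
402,0.00218749111818289
403,0.00291814961940094
404,0.00386592013947281
405,0.00508606923101271
406,0.00664501128274142
407,0.00862170668829955
408,0.0111089965382424
409,0.0142147912067371
410,0.0180630134197815
411,0.0227941808836128
412,0.0285655007845512
413,0.0355503401147828
414,0.0439369336234107
415,0.0539261970306294
416,0.0657285286165431
417,0.0795595087182523
418,0.095634444832586
419,0.114161760009778
420,0.135335283236785
421,0.159325570739541
422,0.186270463698311
423,0.216265166831023
424,0.249352208779397
425,0.285511713642176
426,0.324652467365382
427,0.366604297086407
428,0.411112290530085
429,0.457833361812504
430,0.506335616720616
431,0.55610088390092
432,0.606530659935997
433,0.656955570037221
434,0.706648278526875
435,0.754839603135217
436,0.800737404866576
437,0.843547652357948
438,0.882496908110113
439,0.91685536493746
440,0.945959484136745
441,0.969233259499299
442,0.986207157572277
443,0.996533865126385
444,1.00000010645371
445,0.99653396908292
446,0.986207386701767
447,0.969233659917629
448,0.945960134742912
449,0.91685639058624
450,0.882498499842478
451,0.843550097309792
452,0.80074112956998
453,0.75484523534301
454,0.706656734523685
455,0.656968176754446
456,0.606549324181747
457,0.556128324775689
458,0.506375681945494
459,0.457891454374322
460,0.411195938854417
461,0.366723909957255
462,0.324822324034911
463,0.285751249945812
464,0.249687671405199
465,0.21673171985006
466,0.18691484351827
467,0.16020939704615
468,0.136539143231441
469,0.115790190057928
470,0.0978219359507215
471,0.0824776583376286
472,0.0695944487560032
473,0.0590122662616356
474,0.0505819449061488
475,0.0441720468030806
476,0.0396744973227927
477,0.0370089720903493
478,0.0361260268395626
479,0.0370089720903493
480,0.0396744973227927
481,0.0441720468030806
482,0.0505819449061488
483,0.0590122662616356
484,0.0695944487560032
485,0.0824776583376286
486,0.0978219359507215
487,0.115790190057928
488,0.136539143231441
489,0.16020939704615
490,0.18691484351827
491,0.21673171985006
492,0.249687671405199
493,0.285751249945812
494,0.324822324034911
495,0.366723909957255
496,0.411195938854417
497,0.457891454374322
498,0.506375681945494
499,0.556128324775689
500,0.606549324181747
501,0.656968176754446
502,0.706656734523685
503,0.75484523534301
504,0.80074112956998
505,0.843550097309792
506,0.882498499842478
507,0.91685639058624
508,0.945960134742912
509,0.969233659917629
510,0.986207386701767
511,0.99653396908292
512,1.00000010645371
513,0.996533865126385
514,0.986207157572277
515,0.969233259499299
516,0.945959484136745
517,0.91685536493746
518,0.882496908110113
519,0.843547652357948
520,0.800737404866576
521,0.754839603135217
522,0.706648278526875
523,0.656955570037221
524,0.606530659935997
525,0.55610088390092
526,0.506335616720616
527,0.457833361812504
528,0.411112290530085
529,0.366604297086407
530,0.324652467365382
531,0.285511713642176
532,0.249352208779397
533,0.216265166831024
534,0.186270463698313
535,0.159325570739544
536,0.135335283236792
537,0.11416176000979
538,0.0956344448326106
539,0.0795595087182996
540,0.0657285286166338
541,0.0539261970308018
542,0.0439369336237362
543,0.0355503401153929
544,0.0285655007856872
545,0.0227941808857132
546,0.018063013423638
547,0.0142147912137691
548,0.0111089965509756
549,0.0086217067111969
550,0.00664501132363128
551,0.0050860693035281
552,0.00386592026718396
553,0.00291814984276409
554,0.00218749150613512
555,0.00162843071739982
556,0.00120386114103756
557,0.000883828256702836
558,0.000644383114282718
559,0.000466558545690098
560,0.000335471833333316
561,0.000239551537472602
562,0.000169881699516689
563,0.000119653711941436
564,8.37145032461047e-05
565,5.81990564215336e-05
566,4.02354099437304e-05
567,2.7710960330995e-05
568,1.90899103985907e-05
569,1.32729413240343e-05
570,9.4915201798105e-06
571,7.23061188573817e-06
572,6.17489872962687e-06
573,6.17489872962687e-06
574,7.23061188573817e-06
575,9.4915201798105e-06
576,1.32729413240343e-05
577,1.90899103985907e-05
578,2.7710960330995e-05
579,4.02354099437304e-05
580,5.81990564215336e-05
581,8.37145032461047e-05
582,0.000119653711941436
583,0.000169881699516689
584,0.000239551537472602
585,0.000335471833333316
586,0.000466558545690098
587,0.000644383114282718
588,0.000883828256702836
589,0.00120386114103755
590,0.00162843071739982
591,0.00218749150613512
592,0.00291814984276409
593,0.00386592026718396
594,0.0050860693035281
595,0.00664501132363127
596,0.00862170671119687
597,0.0111089965509755
598,0.014214791213769
599,0.0180630134236378
600,0.0227941808857128
601,0.0285655007856864
602,0.0355503401153913
603,0.0439369336237329
604,0.0539261970307953
605,0.0657285286166211
606,0.0795595087182751
607,0.0956344448325632
608,0.1141617600097
609,0.135335283236619
610,0.159325570739219
611,0.186270463697703
612,0.216265166829888
613,0.249352208777297
614,0.285511713638319
615,0.32465246735835
616,0.366604297073674
617,0.411112290507187
618,0.457833361771614
619,0.506335616648101
620,0.556100883773209
621,0.606530659712633
622,0.656955569649268
623,0.706648277857716
624,0.754839601989007
625,0.800737402916808
626,0.843547649064234
627,0.882496902584595
628,0.916855355732029
629,0.945959468906765
630,0.969233234476344
631,0.986207116743916
632,0.996533798970369
633,1
634,0.996533798970369
635,0.986207116743916
636,0.969233234476344
637,0.945959468906765
638,0.916855355732029
639,0.882496902584595
640,0.843547649064234
641,0.800737402916808
642,0.754839601989007
643,0.706648277857716
644,0.656955569649268
645,0.606530659712633
646,0.556100883773209
647,0.506335616648101
648,0.457833361771614
649,0.411112290507187
650,0.366604297073674
651,0.32465246735835
652,0.285511713638319
653,0.249352208777296
654,0.216265166829887
655,0.186270463697701
656,0.159325570739215
657,0.135335283236613
658,0.114161760009687
659,0.0956344448325386
660,0.0795595087182277
661,0.0657285286165304
662,0.0539261970306229
663,0.0439369336234074
664,0.0355503401147811
665,0.0285655007845504
666,0.0227941808836123
667,0.0180630134197813
668,0.014214791206737
669,0.0111089965382423
670,0.00862170668829952
671,0.0066450112827414
672,0.0050860692310127
673,0.0038659201394728
674,0.00291814961940094
675,0.00218749111818289
676,0.00162843004824121
677,0.0012038599948282
678,0.00088382630693505
679,0.000644379820568608
680,0.000466553020172378
681,0.000335462627902512
682,0.000239536307492858
683,0.00016985667656141
684,0.000119612883581024
685,8.36483472297277e-05
686,5.80926027074228e-05
687,4.00652973929511e-05
688,2.74410024806587e-05
689,1.86644691135205e-05
690,1.26071051770485e-05
691,8.45666596870112e-06
692,5.63335400290385e-06
693,3.72665317207867e-06
694,2.4482455575482e-06
695,1.59725788283431e-06
696,1.03485421110938e-06
697,6.65836146985732e-07
698,4.25441285070183e-07
699,2.69957850336301e-07
700,1.70112550779341e-07
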