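# function: l_cone_opic
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: Govardovskii A1 template (lambda_max 558 nm) x ocular media (lens + macular, age 32), unit peak
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.000603015571
381,0.000656543743
382,0.000713452015
383,0.00077382695
384,0.000837750392
385,0.00090530063
386,0.000976554149
387,0.00105158808
388,0.00113048348
389,0.0012133296
390,0.00130022924
391,0.00139130546
392,0.00148670981
393,0.00158663227
394,0.0016913133
395,0.00180105807
396,0.00191625349
397,0.00203738824
398,0.00216507623
399,0.00230008424
400,0.00244336399
401,0.00259608959
402,0.00275970106
403,0.00293595474
404,0.00312698182
405,0.00333535599
406,0.00356417175
407,0.00381713497
408,0.00409866753
409,0.00441402825
410,0.00476945272
411,0.00500017204
412,0.00526271302
413,0.0055622069
414,0.00590441422
415,0.0062957937
416,0.00674357945
417,0.00725586771
418,0.00784171424
419,0.00851124381
420,0.00927577336
421,0.00987139078
422,0.0105428894
423,0.0112970906
424,0.0121413466
425,0.0130835942
426,0.0141324145
427,0.0152970994
428,0.0165877245
429,0.0180152296
430,0.0195915076
431,0.0208104141
432,0.0221257549
433,0.0235423258
434,0.0250653119
435,0.0267003232
436,0.0284534317
437,0.0303312103
438,0.0323407741
439,0.0344898248
440,0.0367866958
441,0.0385863276
442,0.04047682
443,0.0424619752
444,0.0445459437
445,0.0467332348
446,0.0490287279
447,0.0514376827
448,0.0539657489
449,0.0566189765
450,0.0594038241
451,0.0619408824
452,0.0645882047
453,0.0673510213
454,0.0702348293
455,0.0732453852
456,0.0763886958
457,0.0796710077
458,0.0830987947
459,0.0866787434
460,0.0904177367
461,0.0943445559
462,0.0984465804
463,0.102731286
464,0.107206261
465,0.111879184
466,0.116757784
467,0.121849819
468,0.12716303
469,0.132705113
470,0.138483674
471,0.144240246
472,0.150225501
473,0.156445171
474,0.162904689
475,0.169609143
476,0.176563238
477,0.183771258
478,0.191237028
479,0.198963877
480,0.206954608
481,0.214914349
482,0.223118772
483,0.231567875
484,0.240261034
485,0.249196997
486,0.258373878
487,0.26778916
488,0.2774397
489,0.287321744
490,0.297430938
491,0.307762353
492,0.31831051
493,0.329069405
494,0.340032547
495,0.351192991
496,0.362543376
497,0.374075965
498,0.385782689
499,0.397655184
500,0.409684836
501,0.421862822
502,0.43418015
503,0.446627699
504,0.459196252
505,0.471876533
506,0.484659236
507,0.497535056
508,0.510494708
509,0.523528954
510,0.536628613
511,0.549025551
512,0.561434392
513,0.573846118
514,0.586251854
515,0.598642861
516,0.611010534
517,0.623346396
518,0.635642084
519,0.647889339
520,0.660079993
521,0.672051187
522,0.683944131
523,0.695750883
524,0.707463527
525,0.719074159
526,0.73057486
527,0.741957688
528,0.753214649
529,0.764337688
530,0.775318668
531,0.786149357
532,0.796821412
533,0.807326367
534,0.81765562
535,0.827800428
536,0.837751892
537,0.847500957
538,0.857038406
539,0.866354855
540,0.875440757
541,0.884490039
542,0.893293198
543,0.901840034
544,0.910120194
545,0.918123179
546,0.925838365
547,0.933255013
548,0.940362289
549,0.947149286
550,0.953605044
551,0.959497625
552,0.965034406
553,0.970204699
554,0.974997892
555,0.979403492
556,0.983411159
557,0.98701075
558,0.99019236
559,0.992946369
560,0.995263487
561,0.997134804
562,0.998551842
563,0.999506601
564,0.999991614
565,1
566,0.999525513
567,0.998562596
568,0.997106429
569,0.995152981
570,0.992699056
571,0.98997026
572,0.986735733
573,0.98299469
574,0.978747342
575,0.973994924
576,0.968739724
577,0.962985104
578,0.956735513
579,0.949996498
580,0.942774706
581,0.934862596
582,0.92648809
583,0.9176614
584,0.908393773
585,0.898697458
586,0.888585665
587,0.878072526
588,0.867173041
589,0.855903019
590,0.844279024
591,0.831169205
592,0.81777599
593,0.804118956
594,0.790218038
595,0.776093453
596,0.761765621
597,0.747255083
598,0.732582423
599,0.717768194
600,0.702832841
601,0.68763828
602,0.67236988
603,0.657047394
604,0.641690188
605,0.626317187
606,0.610946827
607,0.595597012
608,0.580285074
609,0.565027744
610,0.549841118
611,0.534863788
612,0.519980508
613,0.505205451
614,0.490552119
615,0.476033333
616,0.461661239
617,0.44744731
618,0.433402356
619,0.419536532
620,0.405859355
621,0.392379716
622,0.379105901
623,0.366045604
624,0.353205953
625,0.340593522
626,0.328214357
627,0.316073988
628,0.304177456
629,0.292529324
630,0.281133693
631,0.269932063
632,0.258994845
633,0.248324665
634,0.237923738
635,0.227793877
636,0.217936501
637,0.208352642
638,0.199042948
639,0.190007688
640,0.181246755
641,0.172799453
642,0.16462137
643,0.156711468
644,0.149068341
645,0.141690214
646,0.134574947
647,0.12772004
648,0.121122636
649,0.11477953
650,0.108687177
651,0.10267607
652,0.0969259426
653,0.0914311018
654,0.0861856015
655,0.0811832613
656,0.0764176883
657,0.0718822996
658,0.0675703461
659,0.0634749375
660,0.0595890679
661,0.0559056415
662,0.052417499
663,0.0491174434
664,0.0459982655
665,0.043052769
666,0.0402737946
667,0.0376542425
668,0.0351870948
669,0.032865435
670,0.030682467
671,0.0286315321
672,0.0267061241
673,0.0248999027
674,0.0232067054
675,0.0216205571
676,0.0201356782
677,0.0187464915
678,0.0174476264
679,0.0162339227
680,0.015100432
681,0.0140424189
682,0.0130553596
683,0.012134941
684,0.011277057
685,0.0104778057
686,0.0097334849
687,0.00904058682
688,0.00839579291
689,0.00779596779
690,0.00723815296
691,0.00671956026
692,0.0062375651
693,0.00578969959
694,0.00537364565
695,0.00498722803
696,0.00462840746
697,0.00429527381
698,0.00398603946
699,0.00369903273
700,0.00343269153
701,0.00318555721
702,0.00295626862
703,0.00274355637
704,0.00254623732
705,0.00236320934
706,0.00219344629
707,0.00203599324
708,0.00188996189
709,0.0017545263
710,0.00162891882
711,0.00151242618
712,0.00140438589
713,0.00130418284
714,0.00121124601
715,0.0011250455
716,0.00104508966
717,0.00097092244
718,0.000902120883
719,0.000838292806
720,0.000779074612
721,0.000724129258
722,0.000673144352
723,0.000625830385
724,0.000581919081
725,0.000541161858
726,0.0005033284
727,0.000468205327
728,0.000435594957
729,0.000405314162
730,0.000377193292
731,0.000351075193
732,0.000326814284
733,0.000304275704
734,0.000283334518
735,0.000263874991
736,0.000245789899
737,0.000228979905
738,0.000213352972
739,0.000198823824
740,0.000185313442
741,0.000172748603
742,0.000161061449
743,0.000150189088
744,0.000140073228
745,0.000130659835
746,0.000121898818
747,0.000113743735
748,0.000106151526
749,9.90822592e-05
750,9.24989035e-05
751,8.63671114e-05
752,8.06550218e-05
753,7.53330769e-05
754,7.0373852e-05
755,6.57518989e-05
756,6.14436e-05
757,5.74270347e-05
758,5.3681854e-05
759,5.0189166e-05
760,4.69314289e-05
761,4.38923526e-05
762,4.10568071e-05
763,3.84107381e-05
764,3.59410887e-05
765,3.3635727e-05
766,3.14833788e-05
767,2.94735656e-05
768,2.7596547e-05
769,2.58432674e-05
770,2.42053067e-05
771,2.26748344e-05
772,2.12445676e-05
773,1.99077312e-05
774,1.86580218e-05
775,1.74895742e-05
776,1.63969297e-05
777,1.53750076e-05
778,1.44190778e-05
779,1.35247365e-05
780,1.26878826e-05
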