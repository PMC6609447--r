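# function: m_cone_opic
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: Govardovskii A1 template (lambda_max 530 nm) x ocular media (lens + macular, age 32), unit peak
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.000454954279
381,0.000487277725
382,0.000521361762
383,0.000557357156
384,0.000595452355
385,0.000635882139
386,0.000678937767
387,0.000724978839
388,0.000774447147
389,0.000827882804
390,0.000885943006
391,0.000949423831
392,0.00101928554
393,0.00109668192
394,0.00118299431
395,0.00127987104
396,0.00138927311
397,0.00151352712
398,0.00165538653
399,0.00181810269
400,0.00200550694
401,0.00222210584
402,0.00247319118
403,0.00276496753
404,0.00310469962
405,0.00350088296
406,0.00396344118
407,0.00450395409
408,0.00513592147
409,0.0058750678
410,0.00673969442
411,0.00749311785
412,0.00834920298
413,0.0093209062
414,0.0104226931
415,0.0116707106
416,0.0130829783
417,0.0146796015
418,0.0164830087
419,0.0185182151
420,0.0208131164
421,0.0227611335
422,0.0248954902
423,0.0272317686
424,0.0297868191
425,0.0325788688
426,0.0356276377
427,0.0389544677
428,0.0425824622
429,0.0465366394
430,0.0508441
431,0.0541826955
432,0.0577232337
433,0.0614763696
434,0.0654534487
435,0.0696665586
436,0.074128585
437,0.078853271
438,0.0838552809
439,0.0891502669
440,0.0947549412
441,0.0990088573
442,0.103429771
443,0.108024702
444,0.112801126
445,0.117766993
446,0.122930737
447,0.128301287
448,0.133888076
449,0.139701045
450,0.145750645
451,0.151105489
452,0.156644216
453,0.162374493
454,0.168304225
455,0.17444152
456,0.180794664
457,0.18737208
458,0.194182296
459,0.201233895
460,0.208535475
461,0.21614536
462,0.224025871
463,0.232185524
464,0.240632631
465,0.249375244
466,0.258421089
467,0.267777493
468,0.277451326
469,0.287448922
470,0.297776013
471,0.307870022
472,0.318263503
473,0.328958199
474,0.33995497
475,0.351253746
476,0.362853479
477,0.374752105
478,0.38694651
479,0.399432503
480,0.412204798
481,0.424669895
482,0.437371448
483,0.450299842
484,0.463444433
485,0.476793578
486,0.49033468
487,0.504054227
488,0.517937854
489,0.5319704
490,0.546135977
491,0.560418039
492,0.574799458
493,0.589262601
494,0.603789413
495,0.618361489
496,0.632960162
497,0.647566571
498,0.662161743
499,0.676726658
500,0.691242317
501,0.705689804
502,0.720050338
503,0.734305322
504,0.748436384
505,0.762425414
506,0.776254589
507,0.789906396
508,0.803363645
509,0.816609477
510,0.829627368
511,0.841238108
512,0.852555922
513,0.863566463
514,0.874255764
515,0.884610222
516,0.894616574
517,0.90426188
518,0.913533502
519,0.922419089
520,0.930906557
521,0.938767891
522,0.946204217
523,0.953204488
524,0.959757902
525,0.965853907
526,0.971482208
527,0.976632774
528,0.981295864
529,0.985462045
530,0.989122221
531,0.992267671
532,0.994890082
533,0.996981595
534,0.998534854
535,0.999543055
536,1
537,0.999900156
538,0.999238711
539,0.998011633
540,0.996215733
541,0.994077588
542,0.991365694
543,0.988079331
544,0.984218843
545,0.979785683
546,0.974782461
547,0.969212977
548,0.963082254
549,0.956396563
550,0.949163435
551,0.941174932
552,0.932661733
553,0.923635519
554,0.914109197
555,0.904096869
556,0.893613792
557,0.882676331
558,0.871301899
559,0.859508896
560,0.847316635
561,0.834745263
562,0.821815676
563,0.808549432
564,0.794968656
565,0.781095942
566,0.76695426
567,0.752566854
568,0.737957143
569,0.723148626
570,0.708164787
571,0.693188597
572,0.678076647
573,0.662851765
574,0.647536445
575,0.632152773
576,0.616722363
577,0.601266299
578,0.58580508
579,0.570358576
580,0.554945992
581,0.539461605
582,0.524054496
583,0.508741646
584,0.493539268
585,0.478462804
586,0.463526924
587,0.448745527
588,0.434131757
589,0.419698009
590,0.405455948
591,0.390876137
592,0.376548117
593,0.362480471
594,0.34868108
595,0.335157151
596,0.321915239
597,0.308961275
598,0.296300581
599,0.283937897
600,0.271877392
601,0.260062797
602,0.248562364
603,0.237378431
604,0.226512813
605,0.215966816
606,0.205741237
607,0.195836372
608,0.18625202
609,0.176987482
610,0.168041568
611,0.159449304
612,0.15116799
613,0.143195186
614,0.135527973
615,0.128162956
616,0.12109628
617,0.114323632
618,0.107840264
619,0.101641006
620,0.0957202849
621,0.0900721504
622,0.0846902977
623,0.0795680963
624,0.07469862
625,0.070074679
626,0.0656888531
627,0.061533527
628,0.0576009252
629,0.0538831486
630,0.0503722098
631,0.0470492336
632,0.0439184359
633,0.0409716463
634,0.0382007482
635,0.0355977087
636,0.0331546062
637,0.0308636555
638,0.028717231
639,0.0267078868
640,0.0248283747
641,0.0230769725
642,0.0214408029
643,0.0199133679
644,0.0184884075
645,0.0171599061
646,0.0159220967
647,0.0147694624
648,0.0136967376
649,0.0126989064
650,0.0117711998
651,0.010891523
652,0.0100757639
653,0.00931958536
654,0.00861890205
655,0.00796987104
656,0.00736888246
657,0.00681254971
658,0.00629769955
659,0.0058213621
660,0.00538076082
661,0.00497330261
662,0.00459656801
663,0.00424830166
664,0.00392640298
665,0.00362891709
666,0.00335402611
667,0.00310004073
668,0.00286539219
669,0.00264862454
670,0.00244838734
671,0.00226342866
672,0.00209258849
673,0.00193479251
674,0.00178904613
675,0.001654429
676,0.00153008975
677,0.00141524107
678,0.00130915516
679,0.00121115938
680,0.00112063223
681,0.00103699965
682,0.000959731425
683,0.000888338
684,0.000822367402
685,0.000761402425
686,0.000705058008
687,0.000652978796
688,0.00060483688
689,0.0005603297
690,0.000519178107
691,0.000481124562
692,0.000445931472
693,0.000413379654
694,0.000383266908
695,0.0003554067
696,0.000329626953
697,0.000305768916
698,0.000283686135
699,0.000263243489
700,0.000244316313
701,0.000226789578
702,0.000210557143
703,0.00019552106
704,0.000181590934
705,0.000168683336
706,0.000156721258
707,0.000145633613
708,0.000135354771
709,0.000125824137
710,0.000116985757
711,0.000108787956
712,0.000101183007
713,9.41268226e-05
714,8.75786727e-05
715,8.15009246e-05
716,7.58588021e-05
717,7.06201647e-05
718,6.57553039e-05
719,6.12367549e-05
720,5.7039124e-05
721,5.31389286e-05
722,4.95144506e-05
723,4.61456002e-05
724,4.30137916e-05
725,4.01018276e-05
726,3.73937932e-05
727,3.48749578e-05
728,3.2531685e-05
729,3.03513492e-05
730,2.83222589e-05
731,2.64335857e-05
732,2.4675299e-05
733,2.3038106e-05
734,2.15133953e-05
735,2.00931864e-05
736,1.87700818e-05
737,1.75372235e-05
738,1.63882521e-05
739,1.53172704e-05
740,1.43188081e-05
741,1.33877905e-05
742,1.25195088e-05
743,1.17095933e-05
744,1.0953988e-05
745,1.02489276e-05
746,9.59091601e-06
747,8.97670658e-06
748,8.40328375e-06
749,7.86784616e-06
750,7.367791e-06
751,6.90069946e-06
752,6.46432341e-06
753,6.05657297e-06
754,5.67550504e-06
755,5.31931268e-06
756,4.98631528e-06
757,4.67494948e-06
758,4.38376074e-06
759,4.11139551e-06
760,3.85659404e-06
761,3.61818364e-06
762,3.39507252e-06
763,3.18624402e-06
764,2.99075127e-06
765,2.80771227e-06
766,2.6363053e-06
767,2.47576466e-06
768,2.32537675e-06
769,2.18447642e-06
770,2.05244353e-06
771,1.92869987e-06
772,1.8127062e-06
773,1.70395955e-06
774,1.60199069e-06
775,1.50636182e-06
776,1.41666437e-06
777,1.33251701e-06
778,1.25356375e-06
779,1.17947224e-06
780,1.10993211e-06
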