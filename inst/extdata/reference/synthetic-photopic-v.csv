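# function: photopic_V
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: 2.444 x L-cone-opic + M-cone-opic, unit peak at 555 nm
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.000584859092
381,0.000634330959
382,0.000686841726
383,0.000742501262
384,0.000801427367
385,0.000863749254
386,0.000929611929
387,0.000999181597
388,0.0010726523
389,0.00115025396
390,0.00123226205
391,0.00131900917
392,0.00141089883
393,0.00150842169
394,0.00161217481
395,0.00172288422
396,0.0018414313
397,0.00196888371
398,0.00210653139
399,0.00225592852
400,0.00241894224
401,0.00259780924
402,0.00279520139
403,0.0030143018
404,0.00325889283
405,0.00353345802
406,0.00384329993
407,0.00419467643
408,0.00459495824
409,0.00505281097
410,0.00557840547
411,0.00597785899
412,0.00643202659
413,0.00694863992
414,0.00753635468
415,0.00820485378
416,0.0089649627
417,0.00982877832
418,0.0108098131
419,0.011923156
420,0.0131856532
421,0.0142177802
422,0.0153626483
423,0.0166300381
424,0.0180305081
425,0.0195754671
426,0.0212772548
427,0.0231492291
428,0.0252058628
429,0.0274628499
430,0.0299372224
431,0.0318529485
432,0.0339013793
433,0.0360892999
434,0.0384239936
435,0.0409132834
436,0.0435655765
437,0.0463899117
438,0.0493960088
439,0.052594322
440,0.0559960948
441,0.0586197602
442,0.0613614031
443,0.0642259696
444,0.0672188028
445,0.0703456554
446,0.073612701
447,0.0770265453
448,0.0805942358
449,0.0843232703
450,0.0882216046
451,0.0917256251
452,0.0953671228
453,0.0991522997
454,0.103087626
455,0.107179828
456,0.111435868
457,0.115862931
458,0.1204684
459,0.125259834
460,0.13024494
461,0.135462735
462,0.14089244
463,0.146542178
464,0.152420093
465,0.158534316
466,0.164892921
467,0.171503876
468,0.178375003
469,0.185513926
470,0.192928019
471,0.200255138
472,0.207842546
473,0.215695021
474,0.223816849
475,0.232211781
476,0.240882985
477,0.249833011
478,0.259063748
479,0.268576393
480,0.278371421
481,0.288050328
482,0.297982274
483,0.308164341
484,0.318592838
485,0.329263308
486,0.340170533
487,0.35130855
488,0.362670674
489,0.374249526
490,0.38603706
491,0.398024607
492,0.410202911
493,0.422562178
494,0.43509212
495,0.447782011
496,0.460620734
497,0.473596836
498,0.486698583
499,0.49991401
500,0.513230971
501,0.526637192
502,0.540120313
503,0.553667935
504,0.567267657
505,0.580907112
506,0.594574
507,0.608256113
508,0.621941358
509,0.635617775
510,0.649273551
511,0.661981835
512,0.674610114
513,0.687147355
514,0.699582745
515,0.711905683
516,0.724105769
517,0.736172797
518,0.748096738
519,0.759867726
520,0.771476041
521,0.782731846
522,0.793800781
523,0.804673611
524,0.815341194
525,0.825794471
526,0.836024453
527,0.846022211
528,0.855778868
529,0.865285593
530,0.874533598
531,0.883514137
532,0.892218507
533,0.900638049
534,0.90876416
535,0.916588295
536,0.92410198
537,0.931296827
538,0.938164545
539,0.944696958
540,0.950886023
541,0.956944167
542,0.962645926
543,0.967983522
544,0.972949386
545,0.977536178
546,0.981736817
547,0.985544495
548,0.988952706
549,0.991955269
550,0.994546345
551,0.996490988
552,0.998012838
553,0.999107515
554,0.999771069
555,1
556,0.999791271
557,0.999142327
558,0.998051108
559,0.996516064
560,0.994536166
561,0.992110922
562,0.989240383
563,0.985925158
564,0.982166422
565,0.977965928
566,0.973326011
567,0.968249601
568,0.962740228
569,0.956802031
570,0.950439762
571,0.943876102
572,0.936896473
573,0.929507215
574,0.921715306
575,0.913528358
576,0.904954621
577,0.89600298
578,0.886682948
579,0.877004661
580,0.86697887
581,0.856419704
582,0.845541286
583,0.834356333
584,0.822878096
585,0.811120336
586,0.799097292
587,0.786823652
588,0.774314517
589,0.761585363
590,0.748652003
591,0.734515067
592,0.720244455
593,0.70585728
594,0.691370704
595,0.676801897
596,0.66216798
597,0.647485973
598,0.632772747
599,0.61804497
600,0.603319058
601,0.588475613
602,0.573672712
603,0.558925701
604,0.544249483
605,0.52965848
606,0.515166597
607,0.500787192
608,0.486533049
609,0.472416355
610,0.45844868
611,0.444743355
612,0.431202022
613,0.417834447
614,0.404649748
615,0.391656401
616,0.378862235
617,0.366274448
618,0.353899609
619,0.341743678
620,0.329812017
621,0.318109412
622,0.30664009
623,0.295407746
624,0.284415559
625,0.273666222
626,0.263161965
627,0.25290458
628,0.242895441
629,0.233135537
630,0.223625485
631,0.214316205
632,0.20526116
633,0.196459816
634,0.187911355
635,0.179614685
636,0.171568454
637,0.163771068
638,0.156220693
639,0.148915271
640,0.141852526
641,0.135061063
642,0.128504063
643,0.122178787
644,0.116082295
645,0.110211446
646,0.104562907
647,0.0991331505
648,0.0939184641
649,0.0889149506
650,0.084118536
651,0.079396899
652,0.074888058
653,0.0705864795
654,0.0664865176
655,0.0625824269
656,0.0588683747
657,0.0553384555
658,0.0519867053
659,0.048807117
660,0.0457936564
661,0.0429402786
662,0.0402409441
663,0.0376896351
664,0.0352803718
665,0.0330072284
666,0.0308643476
667,0.0288459555
668,0.0269463754
669,0.0251600398
670,0.0234815026
671,0.0219054494
672,0.0204267066
673,0.0190402497
674,0.0177412097
675,0.0165248796
676,0.0153867179
677,0.0143223523
678,0.0133275822
679,0.0123983791
680,0.0115308875
681,0.0107214236
682,0.00996647432
683,0.00926269436
684,0.00860690384
685,0.00799608448
686,0.00742737571
687,0.00689807016
688,0.006405609
689,0.00594757681
690,0.00552169638
691,0.00512582327
692,0.00475794033
693,0.00441615213
694,0.0040986794
695,0.00380385347
696,0.00353011083
697,0.00327598776
698,0.00304011499
699,0.00282121267
700,0.00261808531
701,0.00242961702
702,0.00225476684
703,0.00209256432
704,0.00194210521
705,0.00180254741
706,0.0016731071
707,0.00155305499
708,0.00144171288
709,0.00133845027
710,0.00124268127
711,0.00115386162
712,0.00107148586
713,0.000995084747
714,0.000924222759
715,0.000858495762
716,0.000797528847
717,0.000740974282
718,0.000688509603
719,0.000639835831
720,0.000594675801
721,0.000552772605
722,0.000513888142
723,0.000477801762
724,0.000444309006
725,0.000413220434
726,0.000384360531
727,0.000357566691
728,0.000332688277
729,0.00030958574
730,0.000288129807
731,0.000268200726
732,0.000249687563
733,0.000232487554
734,0.000216505499
735,0.000201653202
736,0.000187848959
737,0.000175017068
738,0.000163087392
739,0.000151994944
740,0.000141679504
741,0.000132085266
742,0.000123160513
743,0.000114857309
744,0.000107131224
745,9.99410705e-05
746,9.32486658e-05
747,8.70186072e-05
748,8.12180673e-05
749,7.58166038e-05
750,7.07859825e-05
751,6.6100015e-05
752,6.17344071e-05
753,5.76666193e-05
754,5.38757378e-05
755,5.03423547e-05
756,4.70484573e-05
757,4.39773259e-05
758,4.11134385e-05
759,3.84423838e-05
760,3.59507794e-05
761,3.36261969e-05
762,3.14570922e-05
763,2.94327414e-05
764,2.75431807e-05
765,2.57791516e-05
766,2.41320494e-05
767,2.25938763e-05
768,2.11571972e-05
769,1.98150992e-05
770,1.85611541e-05
771,1.73893833e-05
772,1.62942257e-05
773,1.52705078e-05
774,1.43134158e-05
775,1.34184703e-05
776,1.25815017e-05
777,1.17986292e-05
778,1.10662392e-05
779,1.03809673e-05
780,9.73967994e-06
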