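# function: s_cone_opic
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: Govardovskii A1 template (lambda_max 419 nm) x ocular media (lens + macular, age 32), unit peak
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.00480364093
381,0.00553318534
382,0.00636953703
383,0.00732767843
384,0.0084245955
385,0.0096795306
386,0.0111142649
387,0.0127534332
388,0.0146248751
389,0.016760025
390,0.0191943456
391,0.0219678089
392,0.0251254288
393,0.0287178492
394,0.0328019943
395,0.0374417842
396,0.0427089219
397,0.048683757
398,0.0554562323
399,0.0631269169
400,0.0718081341
401,0.0816251878
402,0.0927176931
403,0.105241017
404,0.119367835
405,0.135289801
406,0.153219353
407,0.173391629
408,0.196066524
409,0.221530876
410,0.250100779
411,0.2727345
412,0.297168999
413,0.323518648
414,0.35190175
415,0.382440297
416,0.415259673
417,0.450488309
418,0.488257292
419,0.528699921
420,0.571951221
421,0.601301176
422,0.631542641
423,0.662651708
424,0.694599841
425,0.727353819
426,0.760875734
427,0.795123021
428,0.830048529
429,0.865600633
430,0.901723386
431,0.915520263
432,0.928536623
433,0.940729076
434,0.952057023
435,0.962482892
436,0.971972347
437,0.980494439
438,0.988021728
439,0.994530341
440,1
441,0.987672024
442,0.974443637
443,0.96035616
444,0.945452851
445,0.929778513
446,0.913379117
447,0.896301448
448,0.878592765
449,0.8603005
450,0.841471991
451,0.817058795
452,0.792478651
453,0.767782309
454,0.743018611
455,0.71823449
456,0.693475003
457,0.668783405
458,0.644201247
459,0.619768492
460,0.595523648
461,0.571635506
462,0.547997526
463,0.524644799
464,0.501611441
465,0.47893065
466,0.456634722
467,0.434755031
468,0.413321965
469,0.392364828
470,0.371911689
471,0.351341421
472,0.331399274
473,0.312105071
474,0.293476418
475,0.275528489
476,0.258273832
477,0.241722184
478,0.225880334
479,0.210752015
480,0.196337846
481,0.182383177
482,0.169170782
483,0.156689131
484,0.14492392
485,0.133858272
486,0.123472976
487,0.113746749
488,0.104656522
489,0.0961777389
490,0.0882846575
491,0.080950646
492,0.0741484733
493,0.0678505834
494,0.0620293499
495,0.0566573087
496,0.0517073657
497,0.0471529782
498,0.0429683108
499,0.0391283644
500,0.0356090801
501,0.0323874205
502,0.029441428
503,0.0267502642
504,0.0242942311
505,0.0220547774
506,0.0200144912
507,0.0181570818
508,0.0164673523
509,0.0149311644
510,0.0135353984
511,0.0122509709
512,0.011086796
513,0.0100320812
514,0.00907691302
515,0.00821220093
516,0.00742962205
517,0.00672156733
518,0.00608108966
519,0.0055018541
520,0.00497809051
521,0.00450351164
522,0.00407457945
523,0.00368693111
524,0.00333660846
525,0.00302002311
526,0.00273392411
527,0.00247536794
528,0.00224169097
529,0.00203048396
530,0.00183956877
531,0.00166697694
532,0.0015109301
533,0.00136982214
534,0.00124220285
535,0.00112676309
536,0.00102232131
537,0.000927811223
538,0.000842270709
539,0.000764831697
540,0.000694711018
541,0.000631347477
542,0.000573931822
543,0.000521892697
544,0.000474714499
545,0.000431931907
546,0.000393124942
547,0.000357914517
548,0.000325958407
549,0.000296947629
550,0.000270603169
551,0.000246616243
552,0.000224826041
553,0.000205025535
554,0.000187027684
555,0.000170663466
556,0.000155780112
557,0.00014223951
558,0.00012991677
559,0.000118698932
560,0.0001084838
561,9.91788942e-05
562,9.07005034e-05
563,8.29728364e-05
564,7.59272528e-05
565,6.95015717e-05
566,6.36394483e-05
567,5.82898124e-05
568,5.34063611e-05
569,4.89471021e-05
570,4.48739417e-05
571,4.11617895e-05
572,3.7768228e-05
573,3.46649704e-05
574,3.18263209e-05
575,2.92289307e-05
576,2.68515772e-05
577,2.4674965e-05
578,2.26815456e-05
579,2.08553545e-05
580,1.9181864e-05
581,1.76437869e-05
582,1.62337938e-05
583,1.49408371e-05
584,1.37548536e-05
585,1.26666743e-05
586,1.16679422e-05
587,1.07510387e-05
588,9.90901548e-06
589,9.13553458e-06
590,8.42481251e-06
591,7.76084102e-06
592,7.15120184e-06
593,6.59129024e-06
594,6.07690477e-06
595,5.60421082e-06
596,5.16970763e-06
597,4.77019827e-06
598,4.40276248e-06
599,4.06473194e-06
600,3.75366783e-06
601,3.46654222e-06
602,3.20223596e-06
603,2.95886944e-06
604,2.73472313e-06
605,2.52822357e-06
606,2.33793051e-06
607,2.16252528e-06
608,2.00080021e-06
609,1.85164897e-06
610,1.71405781e-06
611,1.58746302e-06
612,1.47059331e-06
613,1.36267362e-06
614,1.26299282e-06
615,1.17089829e-06
616,1.08579089e-06
617,1.00712051e-06
618,9.34381855e-07
619,8.67110718e-07
620,8.04880505e-07
621,7.47299092e-07
622,6.94005946e-07
623,6.44669496e-07
624,5.98984724e-07
625,5.56670973e-07
626,5.17469931e-07
627,4.81143792e-07
628,4.47473577e-07
629,4.16257586e-07
630,3.87309996e-07
631,3.60376573e-07
632,3.35393949e-07
633,3.12215349e-07
634,2.90705442e-07
635,2.7073942e-07
636,2.52202149e-07
637,2.34987394e-07
638,2.1899711e-07
639,2.04140786e-07
640,1.90334848e-07
641,1.77542983e-07
642,1.65647523e-07
643,1.54583153e-07
644,1.44289497e-07
645,1.34710726e-07
646,1.25795207e-07
647,1.17495178e-07
648,1.09766442e-07
649,1.02568096e-07
650,9.58622773e-08
651,8.94696013e-08
652,8.35208974e-08
653,7.79841375e-08
654,7.28296876e-08
655,6.80301235e-08
656,6.35600597e-08
657,5.93959933e-08
658,5.55161588e-08
659,5.1900396e-08
660,4.85300269e-08
661,4.53877435e-08
662,4.24575032e-08
663,3.97244337e-08
664,3.71747441e-08
665,3.47956442e-08
666,3.25752685e-08
667,3.05026078e-08
668,2.85674447e-08
669,2.67602951e-08
670,2.50723532e-08
671,2.34954417e-08
672,2.20219653e-08
673,2.06448678e-08
674,1.93575921e-08
675,1.81540444e-08
676,1.70285597e-08
677,1.59758707e-08
678,1.4991079e-08
679,1.40696283e-08
680,1.32072796e-08
681,1.24000883e-08
682,1.16443833e-08
683,1.09367468e-08
684,1.02739969e-08
685,9.65317002e-09
686,9.07150597e-09
687,8.52643315e-09
688,8.0155553e-09
689,7.53663913e-09
690,7.0876028e-09
691,6.66650532e-09
692,6.27153662e-09
693,5.90100845e-09
694,5.55334585e-09
695,5.22707928e-09
696,4.92083734e-09
697,4.63333991e-09
698,4.3633919e-09
699,4.1098774e-09
700,3.87175421e-09
701,3.64804881e-09
702,3.43785167e-09
703,3.24031289e-09
704,3.05463814e-09
705,2.88008488e-09
706,2.71595889e-09
707,2.56161099e-09
708,2.41643401e-09
709,2.27985996e-09
710,2.15135745e-09
711,2.03042919e-09
712,1.91660975e-09
713,1.80946344e-09
714,1.70858234e-09
715,1.61358444e-09
716,1.52411198e-09
717,1.43982981e-09
718,1.36042392e-09
719,1.28560007e-09
720,1.21508247e-09
721,1.14861262e-09
722,1.08594815e-09
723,1.02686179e-09
724,9.71140377e-10
725,9.18583983e-10
726,8.69005029e-10
727,8.22227502e-10
728,7.78086219e-10
729,7.36426134e-10
730,6.97101688e-10
731,6.59976211e-10
732,6.24921356e-10
733,5.91816575e-10
734,5.60548622e-10
735,5.310111e-10
736,5.03104026e-10
737,4.76733434e-10
738,4.51810992e-10
739,4.2825366e-10
740,4.05983353e-10
741,3.84926637e-10
742,3.65014444e-10
743,3.46181797e-10
744,3.28367562e-10
745,3.1151421e-10
746,2.95567597e-10
747,2.80476759e-10
748,2.66193713e-10
749,2.5267328e-10
750,2.39872914e-10
751,2.27752542e-10
752,2.16274412e-10
753,2.0540296e-10
754,1.9510467e-10
755,1.85347959e-10
756,1.76103056e-10
757,1.67341896e-10
758,1.59038017e-10
759,1.51166467e-10
760,1.43703712e-10
761,1.36627555e-10
762,1.29917054e-10
763,1.2355245e-10
764,1.17515098e-10
765,1.117874e-10
766,1.06352744e-10
767,1.0119545e-10
768,9.63007099e-11
769,9.16545416e-11
770,8.72437391e-11
771,8.30558284e-11
772,7.90790249e-11
773,7.53021938e-11
774,7.17148131e-11
775,6.83069383e-11
776,6.50691693e-11
777,6.19926198e-11
778,5.90688876e-11
779,5.62900275e-11
780,5.36485254e-11
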