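# function: melanopic
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: Govardovskii A1 template (lambda_max 480 nm) x lens transmittance (age 32), unit peak
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.000431248295
381,0.000490766116
382,0.000560441561
383,0.000642064634
384,0.000737726719
385,0.000849869464
386,0.000981341455
387,0.00113546391
388,0.00131610681
389,0.001527777
390,0.00177572027
391,0.00206603937
392,0.00240583049
393,0.002803341
394,0.00326815164
395,0.00381138683
396,0.00444595729
397,0.0051868398
398,0.00605139957
399,0.00705976149
400,0.00823523752
401,0.00960481814
402,0.0111997376
403,0.0130561231
404,0.0152157406
405,0.0177268502
406,0.0206451882
407,0.0240350915
408,0.0279707874
409,0.0325378691
410,0.0378349855
411,0.0425121902
412,0.047746874
413,0.0536024536
414,0.0601492018
415,0.0674649449
416,0.0756358269
417,0.084757145
418,0.0949342644
419,0.106283617
420,0.118933793
421,0.129401388
422,0.140723479
423,0.152963404
424,0.166188647
425,0.180471073
426,0.195887159
427,0.212518251
428,0.230450816
429,0.249776713
430,0.270593473
431,0.285873846
432,0.301872384
433,0.318613643
434,0.336122509
435,0.354424171
436,0.373544097
437,0.393508005
438,0.414341826
439,0.436071674
440,0.458723807
441,0.474285009
442,0.490142823
443,0.506292442
444,0.522728516
445,0.539445134
446,0.556435809
447,0.573693458
448,0.591210382
449,0.608978248
450,0.626988063
451,0.641231217
452,0.655492896
453,0.669760065
454,0.684019252
455,0.698256546
456,0.712457586
457,0.726607552
458,0.740691157
459,0.754692643
460,0.768595769
461,0.782563979
462,0.796406215
463,0.810104666
464,0.823641006
465,0.836996403
466,0.850151518
467,0.863086515
468,0.875781072
469,0.888214399
470,0.900365253
471,0.910533163
472,0.920335607
473,0.929752211
474,0.938762449
475,0.947345702
476,0.955481313
477,0.963148657
478,0.970327211
479,0.976996636
480,0.983136864
481,0.987363156
482,0.991009331
483,0.994059168
484,0.996497219
485,0.998308912
486,0.999480666
487,1
488,0.999855647
489,0.999037663
490,0.997537537
491,0.995348296
492,0.992464599
493,0.988882837
494,0.984601207
495,0.979619794
496,0.973940626
497,0.967567728
498,0.960507152
499,0.952767004
500,0.944357441
501,0.935290666
502,0.925580893
503,0.915244308
504,0.904299002
505,0.892764896
506,0.880663646
507,0.868018539
508,0.854854368
509,0.841197303
510,0.82707475
511,0.811393445
512,0.79534741
513,0.778968311
514,0.762288249
515,0.745339596
516,0.728154838
517,0.710766417
518,0.693206587
519,0.675507274
520,0.657699944
521,0.639668183
522,0.621597799
523,0.603518234
524,0.585458049
525,0.567444851
526,0.549505241
527,0.531664771
528,0.513947908
529,0.496378018
530,0.478977349
531,0.461767031
532,0.444767079
533,0.427996402
534,0.411472819
535,0.395213076
536,0.379232864
537,0.363546845
538,0.348168668
539,0.333110988
540,0.318385489
541,0.304072898
542,0.290106534
543,0.276495478
544,0.263247878
545,0.250370956
546,0.237870999
547,0.225753357
548,0.214022434
549,0.202681678
550,0.191733576
551,0.181137933
552,0.170941688
553,0.161144134
554,0.151743587
555,0.142737402
556,0.134121982
557,0.125892804
558,0.118044446
559,0.110570621
560,0.103464225
561,0.0967173792
562,0.0903214941
563,0.0842673267
564,0.0785450489
565,0.0731443187
566,0.0680543536
567,0.0632640065
568,0.0587618413
569,0.0545362092
570,0.0505753226
571,0.0468781194
572,0.0434203583
573,0.040190408
574,0.0371767508
575,0.0343680368
576,0.0317531326
577,0.0293211646
578,0.0270615558
579,0.0249640579
580,0.0230187773
581,0.0212113109
582,0.0195381852
583,0.017990588
584,0.0165601229
585,0.0152388119
586,0.0140190938
587,0.0128938199
588,0.0118562468
589,0.0109000273
590,0.0100191993
591,0.00919545979
592,0.00843836729
593,0.00774278257
594,0.00710392046
595,0.00651733181
596,0.00597888539
597,0.00548475002
598,0.00503137687
599,0.00461548229
600,0.00423403099
601,0.00388332572
602,0.00356182238
603,0.00326711818
604,0.00299700017
605,0.00274943166
606,0.00252253933
607,0.0023146012
608,0.00212403519
609,0.00194938849
610,0.00178932761
611,0.00164300734
612,0.00150886542
613,0.0013858807
614,0.00127311704
615,0.00116971636
616,0.00107489239
617,0.000987924792
618,0.000908153738
619,0.000834974934
620,0.000767835017
621,0.000706227318
622,0.000649687961
623,0.00059779228
624,0.000550151527
625,0.000506409838
626,0.000466241465
627,0.000429348222
628,0.000395457151
629,0.000364318381
630,0.000335703167
631,0.000309330854
632,0.00028509209
633,0.000262809967
634,0.000242322522
635,0.000223481465
636,0.000206151005
637,0.000190206787
638,0.000175534914
639,0.000162031053
640,0.000149599622
641,0.000138184856
642,0.000127669833
643,0.000117981567
644,0.000109053139
645,0.000100823181
646,9.32354105e-05
647,8.6238197e-05
648,7.97841704e-05
649,7.38298621e-05
650,6.83353761e-05
651,6.31622014e-05
652,5.83938318e-05
653,5.39976214e-05
654,4.99436292e-05
655,4.62043894e-05
656,4.27547023e-05
657,3.95714423e-05
658,3.66333833e-05
659,3.39210385e-05
660,3.14165147e-05
661,2.91033779e-05
662,2.6966532e-05
663,2.49921065e-05
664,2.31673546e-05
665,2.14805596e-05
666,1.99209497e-05
667,1.84786192e-05
668,1.71444575e-05
669,1.59100832e-05
670,1.47677843e-05
671,1.37104629e-05
672,1.27315856e-05
673,1.18251365e-05
674,1.09855756e-05
675,1.02077999e-05
676,9.48710797e-06
677,8.81916744e-06
678,8.19998509e-06
679,7.62587964e-06
680,7.0934566e-06
681,6.59958528e-06
682,6.14137769e-06
683,5.71616917e-06
684,5.32150058e-06
685,4.95510197e-06
686,4.61487761e-06
687,4.29889221e-06
688,4.00535825e-06
689,3.73262434e-06
690,3.47916458e-06
691,3.24356869e-06
692,3.02453299e-06
693,2.8208521e-06
694,2.6314113e-06
695,2.45517949e-06
696,2.29120272e-06
697,2.13859824e-06
698,1.99654903e-06
699,1.86429874e-06
700,1.74114705e-06
701,1.62644536e-06
702,1.51959289e-06
703,1.42003304e-06
704,1.32724999e-06
705,1.24076566e-06
706,1.16013686e-06
707,1.08495264e-06
708,1.01483189e-06
709,9.49421082e-07
710,8.88392225e-07
711,8.3144096e-07
712,7.78284796e-07
713,7.28661492e-07
714,6.82327554e-07
715,6.39056856e-07
716,5.98639357e-07
717,5.60879921e-07
718,5.25597224e-07
719,4.92622743e-07
720,4.61799826e-07
721,4.32982825e-07
722,4.06036299e-07
723,3.80834272e-07
724,3.57259555e-07
725,3.35203109e-07
726,3.14563458e-07
727,2.95246153e-07
728,2.7716326e-07
729,2.60232906e-07
730,2.44378837e-07
731,2.29530028e-07
732,2.15620307e-07
733,2.02588013e-07
734,1.90375681e-07
735,1.78929744e-07
736,1.68200259e-07
737,1.58140658e-07
738,1.48707505e-07
739,1.39860286e-07
740,1.315612e-07
741,1.23774974e-07
742,1.16468687e-07
743,1.09611608e-07
744,1.03175045e-07
745,9.71322067e-08
746,9.14580702e-08
747,8.61292612e-08
748,8.11239416e-08
749,7.64217051e-08
750,7.20034798e-08
751,6.78514382e-08
752,6.3948913e-08
753,6.02803192e-08
754,5.68310812e-08
755,5.35875649e-08
756,5.05370155e-08
757,4.7667498e-08
758,4.49678431e-08
759,4.24275964e-08
760,4.00369708e-08
761,3.77868025e-08
762,3.566851e-08
763,3.36740557e-08
764,3.17959102e-08
765,3.00270191e-08
766,2.8360772e-08
767,2.67909734e-08
768,2.53118159e-08
769,2.39178551e-08
770,2.26039858e-08
771,2.13654202e-08
772,2.01976679e-08
773,1.90965162e-08
774,1.80580125e-08
775,1.70784477e-08
776,1.61543409e-08
777,1.52824243e-08
778,1.44596301e-08
779,1.3683078e-08
780,1.29500626e-08
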