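# function: rhodopic
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: Govardovskii A1 template (lambda_max 500 nm) x lens transmittance (age 32), unit peak
# grid: 380-780 nm, 1 nm
wavelength_nm,weight
380,0.00034209312
381,0.000373196922
382,0.00040856273
383,0.000448986861
384,0.000495412801
385,0.000548956115
386,0.000610933417
387,0.000682896067
388,0.000766669355
389,0.000864398096
390,0.00097859965
391,0.00111222561
392,0.00126873352
393,0.00145217032
394,0.00166726931
395,0.00191956284
396,0.00221551334
397,0.00256266539
398,0.0029698224
399,0.00344725158
400,0.00400692182
401,0.00466277946
402,0.00543106795
403,0.00633069827
404,0.00738367768
405,0.00861560611
406,0.0100562503
407,0.0117402076
408,0.0137076731
409,0.0160053256
410,0.0186873506
411,0.0210905287
412,0.0237991608
413,0.0268504473
414,0.030285952
415,0.0341520928
416,0.0385006832
417,0.0433895325
418,0.0488831071
419,0.0550532623
420,0.0619800485
421,0.0678516492
422,0.0742513449
423,0.081223191
424,0.0888146224
425,0.0970766813
426,0.106064259
427,0.11583635
428,0.126456323
429,0.137992202
430,0.150516966
431,0.160115009
432,0.170252386
433,0.180953904
434,0.192245156
435,0.204152529
436,0.216703203
437,0.229925148
438,0.24384713
439,0.258498701
440,0.273910205
441,0.28527705
442,0.29698461
443,0.309036166
444,0.321434693
445,0.334182843
446,0.347282935
447,0.360736939
448,0.374546463
449,0.388712742
450,0.403236625
451,0.415527193
452,0.428003595
453,0.440660489
454,0.453492184
455,0.466492641
456,0.479655476
457,0.492973958
458,0.506441009
459,0.520049202
460,0.533790764
461,0.54778369
462,0.561899861
463,0.576130529
464,0.590466583
465,0.604898545
466,0.619416568
467,0.634010428
468,0.648669521
469,0.663382857
470,0.678139053
471,0.691651082
472,0.705129897
473,0.718563003
474,0.731937577
475,0.745240464
476,0.758458173
477,0.771576869
478,0.784582373
479,0.797460158
480,0.810195342
481,0.821636777
482,0.832872138
483,0.843886342
484,0.854664046
485,0.865189655
486,0.875447336
487,0.885421024
488,0.895094449
489,0.904451144
490,0.91347448
491,0.922147686
492,0.930453884
493,0.938376123
494,0.945897426
495,0.953000827
496,0.95966943
497,0.965886459
498,0.971635322
499,0.976899674
500,0.981663493
501,0.985911146
502,0.989627476
503,0.992797883
504,0.995408405
505,0.997445817
506,0.998897713
507,0.999752602
508,1
509,0.999630524
510,0.998635978
511,0.995632977
512,0.99200058
513,0.987737308
514,0.982843202
515,0.977319877
516,0.971170566
517,0.964400158
518,0.957015221
519,0.949024016
520,0.940436499
521,0.931049903
522,0.921096469
523,0.910591503
524,0.899551867
525,0.887995917
526,0.875943429
527,0.863415508
528,0.850434494
529,0.837023853
530,0.823208065
531,0.8090125
532,0.794463293
533,0.77958721
534,0.764411521
535,0.74896386
536,0.733272098
537,0.717364208
538,0.70126814
539,0.685011698
540,0.668622428
541,0.652277679
542,0.635846384
543,0.619354647
544,0.602827957
545,0.586291107
546,0.569768137
547,0.553282277
548,0.536855904
549,0.520510508
550,0.50426667
551,0.488031654
552,0.471943943
553,0.456021202
554,0.440280144
555,0.424736544
556,0.409405253
557,0.394300217
558,0.3794345
559,0.364820303
560,0.35046899
561,0.336391112
562,0.322596428
563,0.309093927
564,0.295891846
565,0.282997686
566,0.270418228
567,0.258159543
568,0.246226999
569,0.234625265
570,0.223358316
571,0.212478354
572,0.201934175
573,0.191727902
574,0.181860953
575,0.172334043
576,0.163147178
577,0.154299658
578,0.145790073
579,0.137616309
580,0.129775557
581,0.122236176
582,0.115025467
583,0.108138401
584,0.101569332
585,0.0953120294
586,0.0893597145
587,0.0837051002
588,0.0783404348
589,0.0732575497
590,0.0684479092
591,0.0638144385
592,0.0594482072
593,0.0553388521
594,0.05147591
595,0.0478488711
596,0.0444472301
597,0.0412605354
598,0.0382784338
599,0.0354907139
600,0.0328873438
601,0.0304514935
602,0.0281816475
603,0.0260683971
604,0.0241026363
605,0.022275579
606,0.0205787742
607,0.0190041154
608,0.0175438485
609,0.0161905753
610,0.0149372544
611,0.0137803727
612,0.0127099295
613,0.0117199919
614,0.0108049596
615,0.00995955654
616,0.00917882093
617,0.00845809429
618,0.00779300998
619,0.00717948097
620,0.0066136874
621,0.0060920638
622,0.0056112863
623,0.00516825992
624,0.00476010591
625,0.00438414945
626,0.00403790754
627,0.00371907736
628,0.00342552493
629,0.00315527431
630,0.00290649721
631,0.00267688664
632,0.00246559405
633,0.00227116507
634,0.00209225758
635,0.00192763366
636,0.00177615198
637,0.00163676076
638,0.00150849103
639,0.00139045049
640,0.00128181762
641,0.00118210853
642,0.00109031303
643,0.00100579618
644,0.000927973846
645,0.000856308764
646,0.000790306824
647,0.000729513683
648,0.000673511604
649,0.000621916545
650,0.000574375466
651,0.000529709369
652,0.00048860578
653,0.000450774981
654,0.000415951089
655,0.000383890102
656,0.000354368085
657,0.000327179522
658,0.000302135788
659,0.000279063753
660,0.000257804502
661,0.000238212153
662,0.000220152782
663,0.000203503431
664,0.000188151198
665,0.000173992404
666,0.000160931834
667,0.000148882029
668,0.000137762648
669,0.000127499882
670,0.000118025909
671,0.000109278403
672,0.00010120008
673,9.37382829e-05
674,8.68445995e-05
675,8.04745143e-05
676,7.45870883e-05
677,6.91446658e-05
678,6.41126053e-05
679,5.94590329e-05
680,5.51546166e-05
681,5.11723588e-05
682,4.74874059e-05
683,4.40768749e-05
684,4.09196925e-05
685,3.79964492e-05
686,3.52892643e-05
687,3.27816629e-05
688,3.04584621e-05
689,2.83056676e-05
690,2.63103779e-05
691,2.44606971e-05
692,2.27456539e-05
693,2.11551286e-05
694,1.96797846e-05
695,1.83110063e-05
696,1.70408423e-05
697,1.58619522e-05
698,1.47675589e-05
699,1.37514038e-05
700,1.28077062e-05
701,1.19311255e-05
702,1.11167274e-05
703,1.03599514e-05
704,9.65658196e-06
705,9.00272173e-06
706,8.39476672e-06
707,7.82938362e-06
708,7.30348887e-06
709,6.81422938e-06
710,6.35896482e-06
711,5.93525126e-06
712,5.54082616e-06
713,5.17359445e-06
714,4.83161581e-06
715,4.51309287e-06
716,4.21636038e-06
717,3.93987517e-06
718,3.68220696e-06
719,3.44202982e-06
720,3.21811435e-06
721,3.00932041e-06
722,2.81459048e-06
723,2.63294343e-06
724,2.46346887e-06
725,2.30532188e-06
726,2.15771815e-06
727,2.01992951e-06
728,1.89127977e-06
729,1.77114089e-06
730,1.65892947e-06
731,1.55410343e-06
732,1.45615905e-06
733,1.36462809e-06
734,1.27907531e-06
735,1.19909598e-06
736,1.12431372e-06
737,1.05437844e-06
738,9.88964452e-07
739,9.27768695e-07
740,8.70509128e-07
741,8.16923222e-07
742,7.66766563e-07
743,7.19811561e-07
744,6.75846258e-07
745,6.34673218e-07
746,5.96108497e-07
747,5.59980692e-07
748,5.26130058e-07
749,4.94407692e-07
750,4.64674766e-07
751,4.36801828e-07
752,4.10668148e-07
753,3.86161108e-07
754,3.6317564e-07
755,3.41613702e-07
756,3.21383796e-07
757,3.02400513e-07
758,2.84584115e-07
759,2.67860147e-07
760,2.52159073e-07
761,2.37415943e-07
762,2.23570078e-07
763,2.10564782e-07
764,1.98347067e-07
765,1.86867409e-07
766,1.76079509e-07
767,1.65940076e-07
768,1.56408629e-07
769,1.47447302e-07
770,1.39020677e-07
771,1.31095612e-07
772,1.23641096e-07
773,1.16628107e-07
774,1.10029474e-07
775,1.03819763e-07
776,9.7975156e-08
777,9.24733483e-08
778,8.72934473e-08
779,8.24158805e-08
780,7.78223092e-08
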