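# function: blue_light_hazard
# provenance: synthetic (generated by data-raw/make-reference-tables.R)
# construction: piecewise published structure: tabulated rise/decline 380-500 nm, 10^((450-lambda)/50) 500-600 nm, 0.001 600-700 nm
# grid: 380-700 nm, 5 nm
wavelength_nm,weight
380,0.01
385,0.013
390,0.025
395,0.05
400,0.1
405,0.2
410,0.4
415,0.8
420,0.9
425,0.95
430,0.98
435,1
440,1
445,0.97
450,0.94
455,0.9
460,0.8
465,0.7
470,0.62
475,0.55
480,0.45
485,0.4
490,0.22
495,0.16
500,0.1
505,0.0794328235
510,0.0630957344
515,0.0501187234
520,0.0398107171
525,0.0316227766
530,0.0251188643
535,0.0199526231
540,0.0158489319
545,0.0125892541
550,0.01
555,0.00794328235
560,0.00630957344
565,0.00501187234
570,0.00398107171
575,0.00316227766
580,0.00251188643
585,0.00199526231
590,0.00158489319
595,0.00125892541
600,0.001
605,0.001
610,0.001
615,0.001
620,0.001
625,0.001
630,0.001
635,0.001
640,0.001
645,0.001
650,0.001
655,0.001
660,0.001
665,0.001
670,0.001
675,0.001
680,0.001
685,0.001
690,0.001
695,0.001
700,0.001
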