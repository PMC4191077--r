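wavelength_nm,ferrous,ferric,hemichrome
450,3.25,4.689987,3
451,3.151532,4.5449,2.901648
452,3.056064,4.411113,2.806521
453,2.963505,4.288825,2.714512
454,2.873765,4.178271,2.62552
455,2.786759,4.079721,2.539445
456,2.702402,3.993475,2.456192
457,2.620613,3.919861,2.375669
458,2.541314,3.859227,2.297785
459,2.464428,3.811937,2.222455
460,2.389882,3.778362,2.149594
461,2.317604,3.758874,2.079122
462,2.247524,3.753836,2.01096
463,2.179576,3.763592,1.945033
464,2.113694,3.788458,1.881267
465,2.049814,3.828711,1.819592
466,1.987877,3.884575,1.759939
467,1.927821,3.956211,1.702241
468,1.869591,4.043703,1.646435
469,1.813129,4.147051,1.592459
470,1.758382,4.26615,1.540252
471,1.705298,4.400788,1.489756
472,1.653826,4.55063,1.440917
473,1.603917,4.715208,1.393678
474,1.555522,4.893916,1.347989
475,1.508596,5.086,1.303798
476,1.463094,5.290557,1.261057
477,1.418972,5.506527,1.219719
478,1.376188,5.7327,1.179738
479,1.334703,5.967708,1.141072
480,1.294475,6.210042,1.103679
481,1.255468,6.458047,1.067521
482,1.217643,6.709944,1.032561
483,1.180966,6.963834,0.998768
484,1.145402,7.21772,0.966111
485,1.110917,7.469521,0.934568
486,1.07748,7.717097,0.904123
487,1.045059,7.958267,0.874766
488,1.013626,8.19084,0.846502
489,0.983153,8.412634,0.819349
490,0.953613,8.621506,0.793346
491,0.924982,8.815382,0.768556
492,0.897238,8.99228,0.745077
493,0.870361,9.150337,0.723049
494,0.844334,9.287837,0.702664
495,0.819145,9.403235,0.684182
496,0.794784,9.495177,0.667947
497,0.771249,9.56252,0.654402
498,0.748545,9.604347,0.644111
499,0.726686,9.619985,0.637783
500,0.705701,9.609009,0.63629
501,0.685631,9.571251,0.640697
502,0.666543,9.506802,0.652283
503,0.648532,9.416006,0.672558
504,0.631728,9.299462,0.703283
505,0.616314,9.158005,0.746481
506,0.602536,8.992698,0.80443
507,0.590723,8.804818,0.87966
508,0.581312,8.595828,0.97492
509,0.574873,8.367363,1.093138
510,0.572147,8.121203,1.237354
511,0.574078,7.859245,1.410639
512,0.581859,7.583481,1.615987
513,0.596975,7.295966,1.856191
514,0.621244,6.998793,2.133693
515,0.656862,6.694066,2.450434
516,0.706427,6.383872,2.807676
517,0.772956,6.070259,3.205845
518,0.859879,5.755212,3.644362
519,0.971,5.440631,4.121503
520,1.110427,5.128313,4.634289
521,1.282452,4.819936,5.178409
522,1.491391,4.517047,5.748194
523,1.741372,4.221049,6.336656
524,2.036086,3.933196,6.93558
525,2.378494,3.654584,7.535691
526,2.770524,3.386155,8.126883
527,3.212754,3.128689,8.698513
528,3.70413,2.882814,9.23974
529,4.241723,2.649007,9.739914
530,4.820571,2.4276,10.188976
531,5.433614,2.218789,10.577878
532,6.071763,2.022645,10.898965
533,6.724091,1.839122,11.146343
534,7.37817,1.668068,11.316175
535,8.020532,1.509239,11.406901
536,8.637235,1.362309,11.419381
537,9.214496,1.226883,11.356926
538,9.73936,1.102508,11.225231
539,10.200346,0.988685,11.0322
540,10.588022,0.884879,10.787676
541,10.895477,0.790529,10.503082
542,11.118637,0.70506,10.190989
543,11.256419,0.627887,9.864633
544,11.310697,0.558427,9.537399
545,11.286109,0.496101,9.222297
546,11.189704,0.440345,8.931451
547,11.030486,0.390612,8.675629
548,10.818884,0.346375,8.463821
549,10.566188,0.307132,8.302903
550,10.284023,0.272408,8.197379
551,9.98386,0.241756,8.149226
552,9.676629,0.21476,8.157843
553,9.372422,0.191033,8.220102
554,9.080299,0.170217,8.330504
555,8.808199,0.151984,8.481429
556,8.562909,0.136036,8.663464
557,8.350092,0.122102,8.865811
558,8.17433,0.109937,9.076733
559,8.039155,0.09932,9.28404
560,7.947061,0.090056,9.475583
561,7.899462,0.081969,9.639733
562,7.896607,0.074906,9.765833
563,7.937462,0.068729,9.844598
564,8.019563,0.063321,9.868447
565,8.138886,0.058577,9.83175
566,8.289742,0.054407,9.730994
567,8.464752,0.050736,9.564843
568,8.65491,0.047498,9.334117
569,8.849771,0.044639,9.04167
570,9.037759,0.042114,8.692196
571,9.206603,0.039889,8.291964
572,9.343879,0.037937,7.848507
573,9.437615,0.036241,7.370274
574,9.476941,0.03479,6.866268
575,9.45271,0.033586,6.345693
576,9.358053,0.032636,5.817612
577,9.188814,0.031959,5.290651
578,8.943834,0.031583,4.772736
579,8.625044,0.03155,4.270897
580,8.237374,0.031914,3.791115
581,7.788468,0.032743,3.338244
582,7.288244,0.034123,2.915973
583,6.748318,0.036158,2.526845
584,6.181364,0.038973,2.172324
585,5.600424,0.042717,1.85289
586,5.01826,0.047564,1.568158
587,4.446759,0.053717,1.317017
588,3.896452,0.061409,1.097779
589,3.376146,0.070906,0.908316
590,2.892716,0.082505,0.746203
591,2.451015,0.096543,0.608839
592,2.053923,0.113389,0.493558
593,1.702495,0.133448,0.397716
594,1.396195,0.157157,0.318772
595,1.133172,0.184986,0.254335
596,0.910574,0.217429,0.202204
597,0.724847,0.255001,0.160395
598,0.572021,0.298228,0.127144
599,0.447966,0.347642,0.100912
600,0.348588,0.403765,0.080377
601,0.269998,0.467097,0.064417
602,0.208617,0.538105,0.052093
603,0.161245,0.617203,0.04263
604,0.125098,0.704735,0.035397
605,0.097806,0.800961,0.029885
606,0.077396,0.906033,0.025691
607,0.062257,1.019983,0.022494
608,0.051101,1.142703,0.020048
609,0.042914,1.273927,0.018162
610,0.036914,1.413223,0.01669
611,0.032503,1.559981,0.015524
612,0.029237,1.713405,0.014581
613,0.026787,1.872509,0.013802
614,0.024914,2.036127,0.013142
615,0.023445,2.202911,0.01257
616,0.02226,2.371351,0.012063
617,0.021274,2.53979,0.011603
618,0.020427,2.70645,0.01118
619,0.019679,2.869457,0.010785
620,0.019002,3.026878,0.010414
621,0.018378,3.176757,0.01006
622,0.017795,3.317153,0.009723
623,0.017243,3.446183,0.009399
624,0.016716,3.562062,0.009088
625,0.016212,3.663144,0.008788
626,0.015727,3.747964,0.008499
627,0.015258,3.815267,0.00822
628,0.014806,3.864046,0.00795
629,0.014368,3.89356,0.007689
630,0.013944,3.90336,0.007437
631,0.013533,3.893292,0.007193
632,0.013134,3.863508,0.006957
633,0.012748,3.814459,0.006729
634,0.012373,3.746884,0.006508
635,0.012009,3.661791,0.006295
636,0.011656,3.560434,0.006088
637,0.011313,3.444277,0.005889
638,0.010981,3.314966,0.005696
639,0.010659,3.174286,0.005509
640,0.010346,3.024118,0.005328
641,0.010042,2.866404,0.005154
642,0.009747,2.703099,0.004985
643,0.009461,2.536137,0.004821
644,0.009183,2.367389,0.004663
645,0.008914,2.198633,0.00451
646,0.008652,2.031527,0.004362
647,0.008399,1.86758,0.004219
648,0.008152,1.708138,0.004081
649,0.007913,1.554369,0.003947
650,0.007681,1.407256,0.003818
651,0.007456,1.267595,0.003693
652,0.007238,1.135996,0.003572
653,0.007026,1.012892,0.003455
654,0.00682,0.898545,0.003341
655,0.00662,0.793064,0.003232
656,0.006426,0.696417,0.003126
657,0.006238,0.60845,0.003023
658,0.006055,0.528904,0.002924
659,0.005878,0.457432,0.002828
660,0.005706,0.393621,0.002736
661,0.005539,0.337002,0.002646
662,0.005376,0.287076,0.002559
663,0.005219,0.243317,0.002475
664,0.005066,0.205196,0.002394
665,0.004918,0.172183,0.002316
666,0.004774,0.143762,0.00224
667,0.004635,0.119439,0.002166
668,0.004499,0.098744,0.002095
669,0.004368,0.081236,0.002027
670,0.00424,0.06651,0.00196
671,0.004116,0.054194,0.001896
672,0.003996,0.043951,0.001834
673,0.003879,0.035481,0.001774
674,0.003765,0.028515,0.001715
675,0.003655,0.022818,0.001659
676,0.003549,0.018184,0.001605
677,0.003445,0.014435,0.001552
678,0.003344,0.011419,0.001501
679,0.003247,0.009004,0.001452
680,0.003152,0.007082,0.001405
681,0.00306,0.005559,0.001358
682,0.002971,0.004358,0.001314
683,0.002884,0.003416,0.001271
684,0.0028,0.002681,0.001229
685,0.002718,0.002109,0.001189
686,0.002639,0.001666,0.00115
687,0.002562,0.001324,0.001112
688,0.002487,0.001061,0.001076
689,0.002414,0.00086,0.00104
690,0.002344,0.000705,0.001006
691,0.002276,0.000587,0.000973
692,0.002209,0.000496,0.000941
693,0.002145,0.000427,0.000911
694,0.002082,0.000373,0.000881
695,0.002022,0.000331,0.000852
696,0.001963,0.000298,0.000824
697,0.001906,0.000272,0.000797
698,0.00185,0.000251,0.000771
699,0.001796,0.000233,0.000746
700,0.001744,0.000219,0.000721
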