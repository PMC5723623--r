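scenario,model,lnl,k,d,e,j,aic,aic_wt
null,BAYAREALIKE,-1480.99,2,0.00389,0.019351951,0,2965.992259,3.63e-96
null,BAYAREALIKE+J,-1260.30,3,0.00228,0.000617994,0.046701184,2526.614158,0.933204519
null,DEC,-1318.92,2,0.00449,1.00e-12,0,2641.850873,8.84e-26
null,DEC+J,-1262.94,3,0.00356,1.00e-12,0.028423902,2531.888136,0.066795481
null,DIVALIKE,-1330.90,2,0.00541,1.00e-12,0,2665.809754,5.55e-31
null,DIVALIKE+J,-1294.20,3,0.00428,1.08e-09,0.022922813,2594.403385,1.78e-15
complex1,BAYAREALIKE,-1465.10,2,0.01131,0.016440112,0,2934.215946,3.10e-106
complex1,BAYAREALIKE+J,-1235.58,3,0.00847,0.000807486,0.126630982,2477.169101,5.48e-07
complex1,DEC,-1288.10,2,0.01513,0.000614288,0,2580.218724,2.30e-29
complex1,DEC+J,-1221.16,3,0.01144,4.87e-05,0.115873802,2448.333573,0.999999452
complex1,DIVALIKE,-1295.18,2,0.018188,0.000809571,0,2594.36264,1.95e-32
complex1,DIVALIKE+J,-1272.81,3,0.014687,0.000472286,0.020573461,2551.631877,3.71e-23
complex2,BAYAREALIKE,-1468.83,2,0.01044,0.016429327,0,2941.666889,8.73e-102
complex2,BAYAREALIKE+J,-1243.37,3,0.00805,0.000673963,0.122983955,2492.751708,0.00026405
complex2,DEC,-1296.90,2,0.01430,0.00060304,0,2597.809953,4.06e-27
complex2,DEC+J,-1235.13,3,0.01109,5.33e-05,0.063058035,2476.273491,0.99973595
complex2,DIVALIKE,-1304.63,2,0.01719,0.000805488,0,2613.262891,1.79e-30
complex2,DIVALIKE+J,-1281.03,3,0.01505,0.000812842,0.019658281,2568.078678,1.16e-20
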