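# medium: water
# mean excitation energy I = 78 eV; Z/A = 0.55509; density = 1 g/cm3
# columns: energy_mev  stopping_mev_cm2_g  csda_g_cm2 (unit density mass units)
# proton electronic stopping, Bethe formula with Barkas effective charge;
# continued as S ~ sqrt(E) below the stopping maximum; range integral cutoff 20 keV
energy_mev	stopping_mev_cm2_g	csda_g_cm2
2.0000000e-02	2.2784389e+02	0.0000000e+00
2.1404455e-02	2.3570809e+02	6.0595345e-06
2.2907534e-02	2.4384372e+02	1.2328218e-05
2.4516164e-02	2.5226015e+02	1.8813270e-05
2.6237756e-02	2.6096709e+02	2.5522158e-05
2.8080243e-02	2.6997455e+02	3.2462609e-05
3.0052114e-02	2.7929291e+02	3.9642614e-05
3.2162456e-02	2.8893290e+02	4.7070442e-05
3.4420992e-02	2.9890562e+02	5.4754647e-05
3.6838128e-02	3.0922256e+02	6.2704076e-05
3.9425002e-02	3.1989559e+02	7.0927886e-05
4.2193533e-02	3.3093701e+02	7.9435546e-05
4.5156479e-02	3.4235954e+02	8.8236855e-05
4.8327490e-02	3.5417632e+02	9.7341947e-05
5.1721179e-02	3.6640096e+02	1.0676131e-04
5.5353181e-02	3.7904755e+02	1.1650578e-04
5.9240233e-02	3.9213064e+02	1.2658660e-04
6.3400244e-02	4.0566530e+02	1.3701536e-04
6.7852383e-02	4.1966712e+02	1.4780407e-04
7.2617163e-02	4.3415223e+02	1.5896517e-04
7.7716539e-02	4.4913730e+02	1.7051150e-04
8.3174007e-02	4.6463959e+02	1.8245636e-04
8.9014713e-02	4.8067695e+02	1.9481350e-04
9.5265570e-02	4.9726785e+02	2.0759716e-04
1.0195538e-01	5.1443140e+02	2.2082206e-04
1.0911496e-01	5.3218736e+02	2.3450342e-04
1.1677732e-01	5.5055618e+02	2.4865701e-04
1.2497774e-01	5.6955901e+02	2.6329911e-04
1.3375402e-01	5.8921774e+02	2.7844660e-04
1.4314659e-01	6.0955500e+02	2.9409360e-04
1.5319873e-01	6.0852217e+02	3.1057226e-04
1.6395677e-01	6.0560777e+02	3.2828976e-04
1.7547026e-01	6.0095961e+02	3.4737101e-04
1.8779226e-01	5.9472425e+02	3.6797886e-04
2.0097955e-01	5.8704624e+02	3.9029435e-04
2.1509288e-01	5.7806741e+02	4.1451921e-04
2.3019729e-01	5.6792622e+02	4.4087871e-04
2.4636238e-01	5.5675711e+02	4.6962481e-04
2.6366262e-01	5.4468993e+02	5.0103965e-04
2.8217773e-01	5.3184941e+02	5.3543958e-04
3.0199302e-01	5.1835469e+02	5.7317965e-04
3.2319980e-01	5.0431895e+02	6.1465861e-04
3.4589577e-01	4.8984905e+02	6.6032465e-04
3.7018552e-01	4.7504527e+02	7.1068181e-04
3.9618096e-01	4.6000116e+02	7.6629725e-04
4.2400187e-01	4.4480337e+02	8.2780941e-04
4.5377644e-01	4.2953161e+02	8.9593725e-04
4.8564186e-01	4.1425868e+02	9.7149071e-04
5.1974496e-01	3.9905055e+02	1.0553824e-03
5.5624287e-01	3.8396645e+02	1.1486411e-03
5.9530377e-01	3.6905910e+02	1.2524264e-03
6.3710763e-01	3.5437489e+02	1.3680460e-03
6.8184707e-01	3.3995422e+02	1.4969745e-03
7.2972824e-01	3.2583175e+02	1.6408754e-03
7.8097175e-01	3.1203674e+02	1.8016252e-03
8.3581372e-01	2.9859342e+02	1.9813409e-03
8.9450685e-01	2.8552135e+02	2.1824115e-03
9.5732157e-01	2.7283580e+02	2.4075328e-03
1.0245473e+00	2.6054811e+02	2.6597474e-03
1.0964938e+00	2.4866609e+02	2.9424898e-03
1.1734926e+00	2.3719437e+02	3.2596367e-03
1.2558985e+00	2.2613478e+02	3.6155651e-03
1.3440911e+00	2.1548665e+02	4.0152172e-03
1.4384769e+00	2.0524716e+02	4.4641737e-03
1.5394906e+00	1.9541167e+02	4.9687377e-03
1.6475979e+00	1.8597393e+02	5.5360282e-03
1.7632967e+00	1.7692640e+02	6.1740876e-03
1.8871202e+00	1.6826045e+02	6.8920019e-03
2.0196390e+00	1.5996661e+02	7.7000375e-03
2.1614635e+00	1.5203470e+02	8.6097965e-03
2.3132474e+00	1.4445405e+02	9.6343913e-03
2.4756900e+00	1.3721362e+02	1.0788644e-02
2.6495397e+00	1.3030212e+02	1.2089309e-02
2.8355976e+00	1.2370814e+02	1.3555333e-02
3.0347211e+00	1.1742024e+02	1.5208135e-02
3.2478275e+00	1.1142699e+02	1.7071939e-02
3.4758988e+00	1.0571709e+02	1.9174142e-02
3.7199859e+00	1.0027939e+02	2.1545731e-02
3.9812135e+00	9.5102908e+01	2.4221757e-02
4.2607852e+00	9.0176927e+01	2.7241875e-02
4.5599892e+00	8.5490969e+01	3.0650944e-02
4.8802041e+00	8.1034832e+01	3.4499723e-02
5.2229054e+00	7.6798606e+01	3.8845640e-02
5.5896721e+00	7.2772680e+01	4.3753684e-02
5.9821942e+00	6.8947752e+01	4.9297388e-02
6.4022802e+00	6.5314826e+01	5.5559970e-02
6.8518659e+00	6.1865221e+01	6.2635601e-02
7.3330226e+00	5.8590564e+01	7.0630854e-02
7.8479675e+00	5.5482790e+01	7.9666335e-02
8.3990733e+00	5.2534140e+01	8.9878533e-02
8.9888792e+00	4.9737151e+01	1.0142191e-01
9.6201029e+00	4.7084658e+01	1.1447126e-01
1.0295653e+01	4.4569779e+01	1.2922438e-01
1.1018642e+01	4.2185915e+01	1.4590509e-01
1.1792401e+01	3.9926742e+01	1.6476666e-01
1.2620496e+01	3.7786200e+01	1.8609561e-01
1.3506741e+01	3.5758488e+01	2.1021613e-01
1.4455222e+01	3.3838057e+01	2.3749493e-01
1.5470307e+01	3.2019598e+01	2.6834680e-01
1.6556674e+01	3.0298039e+01	3.0324088e-01
1.7719329e+01	2.8668536e+01	3.4270764e-01
1.8963629e+01	2.7126462e+01	3.8734687e-01
2.0295307e+01	2.5667400e+01	4.3783660e-01
2.1720499e+01	2.4287140e+01	4.9494315e-01
2.3245771e+01	2.2981666e+01	5.5953246e-01
2.4878153e+01	2.1747149e+01	6.3258276e-01
2.6625165e+01	2.0579942e+01	7.1519894e-01
2.8494857e+01	1.9476571e+01	8.0862854e-01
3.0495844e+01	1.8433731e+01	9.1427971e-01
3.2637345e+01	1.7448273e+01	1.0337414e+00
3.4929229e+01	1.6517203e+01	1.1688059e+00
3.7382055e+01	1.5637674e+01	1.3214941e+00
4.0007125e+01	1.4806978e+01	1.4940838e+00
4.2816535e+01	1.4022542e+01	1.6891408e+00
4.5823229e+01	1.3281921e+01	1.9095544e+00
4.9041062e+01	1.2582792e+01	2.1585762e+00
5.2484859e+01	1.1922949e+01	2.4398635e+00
5.6170489e+01	1.1300300e+01	2.7575270e+00
6.0114935e+01	1.0712857e+01	3.1161850e+00
6.4336370e+01	1.0158734e+01	3.5210214e+00
6.8854246e+01	9.6361432e+00	3.9778510e+00
7.3689379e+01	9.1433886e+00	4.4931914e+00
7.8864049e+01	8.6788623e+00	5.0743411e+00
8.4402098e+01	8.2410403e+00	5.7294660e+00
9.0329045e+01	7.8284785e+00	6.4676938e+00
9.6672197e+01	7.4398088e+00	7.2992162e+00
1.0346078e+02	7.0737357e+00	8.2354008e+00
1.1072608e+02	6.7290321e+00	9.2889124e+00
1.1850157e+02	6.4045369e+00	1.0473843e+01
1.2682308e+02	6.0991508e+00	1.1805854e+01
1.3572894e+02	5.8118339e+00	1.3302323e+01
1.4526020e+02	5.5416024e+00	1.4982511e+01
1.5546076e+02	5.2875260e+00	1.6867726e+01
1.6637764e+02	5.0487250e+00	1.8981508e+01
1.7806114e+02	4.8243679e+00	2.1349820e+01
1.9056508e+02	4.6136689e+00	2.4001243e+01
2.0394708e+02	4.4158854e+00	2.6967184e+01
2.1826880e+02	4.2303161e+00	3.0282091e+01
2.3359623e+02	4.0562986e+00	3.3983673e+01
2.5000000e+02	3.8932074e+00	3.8112944e+01
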