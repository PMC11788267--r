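# medium: pmma
# mean excitation energy I = 74 eV; Z/A = 0.53937; density = 1.19 g/cm3
# columns: energy_mev  stopping_mev_cm2_g  csda_g_cm2 (unit density mass units)
# proton electronic stopping, Bethe formula with Barkas effective charge;
# continued as S ~ sqrt(E) below the stopping maximum; range integral cutoff 20 keV
energy_mev	stopping_mev_cm2_g	csda_g_cm2
2.0000000e-02	2.3779343e+02	0.0000000e+00
2.1404455e-02	2.4600104e+02	5.8059969e-06
2.2907534e-02	2.5449194e+02	1.1812392e-05
2.4516164e-02	2.6327591e+02	1.8026102e-05
2.6237756e-02	2.7236306e+02	2.4454283e-05
2.8080243e-02	2.8176386e+02	3.1104337e-05
3.0052114e-02	2.9148914e+02	3.7983923e-05
3.2162456e-02	3.0155009e+02	4.5100962e-05
3.4420992e-02	3.1195830e+02	5.2463652e-05
3.6838128e-02	3.2272576e+02	6.0080468e-05
3.9425002e-02	3.3386487e+02	6.7960184e-05
4.2193533e-02	3.4538845e+02	7.6111875e-05
4.5156479e-02	3.5730977e+02	8.4544927e-05
4.8327490e-02	3.6964257e+02	9.3269052e-05
5.1721179e-02	3.8240104e+02	1.0229430e-04
5.5353181e-02	3.9559988e+02	1.1163105e-04
5.9240233e-02	4.0925429e+02	1.2129008e-04
6.3400244e-02	4.2337999e+02	1.3128248e-04
6.7852383e-02	4.3799325e+02	1.4161979e-04
7.2617163e-02	4.5311089e+02	1.5231389e-04
7.7716539e-02	4.6875033e+02	1.6337711e-04
8.3174007e-02	4.8492958e+02	1.7482218e-04
8.9014713e-02	5.0166726e+02	1.8666229e-04
9.5265570e-02	5.1898266e+02	1.9891107e-04
1.0195538e-01	5.3689571e+02	2.1158262e-04
1.0911496e-01	5.5542704e+02	2.2469154e-04
1.1677732e-01	5.7459799e+02	2.3825292e-04
1.2497774e-01	5.9443065e+02	2.5228239e-04
1.3375402e-01	6.1494784e+02	2.6677537e-04
1.4314659e-01	6.1479656e+02	2.8202744e-04
1.5319873e-01	6.1270605e+02	2.9840182e-04
1.6395677e-01	6.0882097e+02	3.1601245e-04
1.7547026e-01	6.0328537e+02	3.3500693e-04
1.8779226e-01	5.9624198e+02	3.5554919e-04
2.0097955e-01	5.8783149e+02	3.7782172e-04
2.1509288e-01	5.7819182e+02	4.0202815e-04
2.3019729e-01	5.6745750e+02	4.2839607e-04
2.4636238e-01	5.5575906e+02	4.5718022e-04
2.6366262e-01	5.4322247e+02	4.8866607e-04
2.8217773e-01	5.2996860e+02	5.2317389e-04
3.0199302e-01	5.1611283e+02	5.6106328e-04
3.2319980e-01	5.0176462e+02	6.0273831e-04
3.4589577e-01	4.8702724e+02	6.4865330e-04
3.7018552e-01	4.7199749e+02	6.9931936e-04
3.9618096e-01	4.5676552e+02	7.5531180e-04
4.2400187e-01	4.4141475e+02	8.1727841e-04
4.5377644e-01	4.2602181e+02	8.8594888e-04
4.8564186e-01	4.1065653e+02	9.6214546e-04
5.1974496e-01	3.9538207e+02	1.0467949e-03
5.5624287e-01	3.8025504e+02	1.1409419e-03
5.9530377e-01	3.6532566e+02	1.2457646e-03
6.3710763e-01	3.5063803e+02	1.3625917e-03
6.8184707e-01	3.3623035e+02	1.4929219e-03
7.2972824e-01	3.2213528e+02	1.6384461e-03
7.8097175e-01	3.0838024e+02	1.8010719e-03
8.3581372e-01	2.9498776e+02	1.9829523e-03
8.9450685e-01	2.8197582e+02	2.1865168e-03
9.5732157e-01	2.6935828e+02	2.4145076e-03
1.0245473e+00	2.5714519e+02	2.6700202e-03
1.0964938e+00	2.4534318e+02	2.9565492e-03
1.1734926e+00	2.3395586e+02	3.2780401e-03
1.2558985e+00	2.2298408e+02	3.6389478e-03
1.3440911e+00	2.1242636e+02	4.0443035e-03
1.4384769e+00	2.0227913e+02	4.4997893e-03
1.5394906e+00	1.9253708e+02	5.0118232e-03
1.6475979e+00	1.8319339e+02	5.5876555e-03
1.7632967e+00	1.7424002e+02	6.2354778e-03
1.8871202e+00	1.6566791e+02	6.9645459e-03
2.0196390e+00	1.5746717e+02	7.7853192e-03
2.1614635e+00	1.4962733e+02	8.7096194e-03
2.3132474e+00	1.4213743e+02	9.7508090e-03
2.4756900e+00	1.3498619e+02	1.0923994e-02
2.6495397e+00	1.2816213e+02	1.2246253e-02
2.8355976e+00	1.2165368e+02	1.3736898e-02
3.0347211e+00	1.1544925e+02	1.5417768e-02
3.2478275e+00	1.0953733e+02	1.7313563e-02
3.4758988e+00	1.0390652e+02	1.9452219e-02
3.7199859e+00	9.8545612e+01	2.1865338e-02
3.9812135e+00	9.3443593e+01	2.4588670e-02
4.2607852e+00	8.8589707e+01	2.7662663e-02
4.5599892e+00	8.3973466e+01	3.1133082e-02
4.8802041e+00	7.9584670e+01	3.5051709e-02
5.2229054e+00	7.5413418e+01	3.9477142e-02
5.5896721e+00	7.1450118e+01	4.4475694e-02
5.9821942e+00	6.7685495e+01	5.0122408e-02
6.4022802e+00	6.4110588e+01	5.6502212e-02
6.8518659e+00	6.0716753e+01	6.3711227e-02
7.3330226e+00	5.7495662e+01	7.1858236e-02
7.8479675e+00	5.4439299e+01	8.1066359e-02
8.3990733e+00	5.1539955e+01	9.1474940e-02
8.9888792e+00	4.8790221e+01	1.0324168e-01
9.6201029e+00	4.6182987e+01	1.1654507e-01
1.0295653e+01	4.3711430e+01	1.3158708e-01
1.1018642e+01	4.1369008e+01	1.4859629e-01
1.1792401e+01	3.9149457e+01	1.6783135e-01
1.2620496e+01	3.7046775e+01	1.8958493e-01
1.3506741e+01	3.5055222e+01	2.1418814e-01
1.4455222e+01	3.3169306e+01	2.4201559e-01
1.5470307e+01	3.1383779e+01	2.7349104e-01
1.6556674e+01	2.9693626e+01	3.0909375e-01
1.7719329e+01	2.8094061e+01	3.4936574e-01
1.8963629e+01	2.6580511e+01	3.9491986e-01
2.0295307e+01	2.5148618e+01	4.4644893e-01
2.1720499e+01	2.3794224e+01	5.0473606e-01
2.3245771e+01	2.2513365e+01	5.7066620e-01
2.4878153e+01	2.1302265e+01	6.4523915e-01
2.6625165e+01	2.0157326e+01	7.2958416e-01
2.8494857e+01	1.9075124e+01	8.2497640e-01
3.0495844e+01	1.8052400e+01	9.3285528e-01
3.2637345e+01	1.7086051e+01	1.0548451e+00
3.4929229e+01	1.6173128e+01	1.1927781e+00
3.7382055e+01	1.5310825e+01	1.3487204e+00
4.0007125e+01	1.4496478e+01	1.5250007e+00
4.2816535e+01	1.3727551e+01	1.7242427e+00
4.5823229e+01	1.3001639e+01	1.9494005e+00
4.9041062e+01	1.2316455e+01	2.2037991e+00
5.2484859e+01	1.1669830e+01	2.4911785e+00
5.6170489e+01	1.1059704e+01	2.8157426e+00
6.0114935e+01	1.0484123e+01	3.1822145e+00
6.4336370e+01	9.9412329e+00	3.5958960e+00
6.8854246e+01	9.4292749e+00	4.0627346e+00
7.3689379e+01	8.9465821e+00	4.5893965e+00
7.8864049e+01	8.4915743e+00	5.1833474e+00
8.4402098e+01	8.0627539e+00	5.8529406e+00
9.0329045e+01	7.6587020e+00	6.6075133e+00
9.6672197e+01	7.2780748e+00	7.4574918e+00
1.0346078e+02	6.9195994e+00	8.4145059e+00
1.1072608e+02	6.5820712e+00	9.4915129e+00
1.1850157e+02	6.2643496e+00	1.0702931e+01
1.2682308e+02	5.9653555e+00	1.2064784e+01
1.3572894e+02	5.6840681e+00	1.3594855e+01
1.4526020e+02	5.4195216e+00	1.5312851e+01
1.5546076e+02	5.1708030e+00	1.7240578e+01
1.6637764e+02	4.9370491e+00	1.9402127e+01
1.7806114e+02	4.7174439e+00	2.1824065e+01
1.9056508e+02	4.5112165e+00	2.4535645e+01
2.0394708e+02	4.3176385e+00	2.7569011e+01
2.1826880e+02	4.1360219e+00	3.0959422e+01
2.3359623e+02	3.9657171e+00	3.4745475e+01
2.5000000e+02	3.8061105e+00	3.8969152e+01
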