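element,coefficient,exponent,n_elec
H,7.889905488729e-04,7.525000000000e-02,1
H,6.141914073908e-02,1.617875000000e-01,1
H,3.552410319901e-01,3.478431250000e-01,1
H,3.602251238418e-01,7.478627187500e-01,1
H,1.585477528062e-01,1.607904845312e+00,1
H,4.808057493879e-02,3.456995417422e+00,1
H,1.206508644564e-02,7.432540147457e+00,1
H,2.829198862882e-03,1.597996131703e+01,1
H,6.251038940247e-04,3.435691683162e+01,1
H,1.398648307629e-04,7.386737118798e+01,1
H,2.964845701490e-05,1.588148480542e+02,1
H,6.720297313298e-06,3.414519233165e+02,1
H,1.351146065247e-06,7.341216351304e+02,1
H,3.354218476101e-07,1.578361515530e+03,1
H,5.294084427683e-08,3.393477258390e+03,1
H,2.110155831628e-08,7.295976105539e+03,1
H,1.737182359368e-09,3.372564954785e+04,1
Be,1.550286584891e+00,1.617875000000e-01,4
Be,5.235053673808e-01,3.478431250000e-01,4
Be,4.125102120958e-01,3.456995417422e+00,4
Be,8.371717358467e-01,7.432540147457e+00,4
Be,4.584244649880e-01,1.597996131703e+01,4
Be,1.632002028034e-01,3.435691683162e+01,4
Be,4.147050719955e-02,7.386737118798e+01,4
Be,1.056176437121e-02,1.588148480542e+02,4
Be,2.192133951210e-03,3.414519233165e+02,4
Be,5.407089255718e-04,7.341216351304e+02,4
Be,1.048959707048e-04,1.578361515530e+03,4
Be,2.410342142246e-05,3.393477258390e+03,4
Be,6.459304462038e-06,7.295976105539e+03,4
Be,2.546788275577e-07,1.568634862691e+04,4
Be,6.041718862309e-07,3.372564954785e+04,4
C,1.797649707147e+00,3.478431250000e-01,6
C,2.338932124435e+00,7.478627187500e-01,6
C,2.425369059618e-01,7.432540147457e+00,6
C,8.631633164083e-01,1.597996131703e+01,6
C,5.003428543644e-01,3.435691683162e+01,6
C,1.926072451073e-01,7.386737118798e+01,6
C,4.838266347512e-02,1.588148480542e+02,6
C,1.300987500177e-02,3.414519233165e+02,6
C,2.519028905454e-03,7.341216351304e+02,6
C,7.093427303234e-04,1.578361515530e+03,6
C,9.916673748839e-05,3.393477258390e+03,6
C,4.424830295799e-05,7.295976105539e+03,6
C,3.521422671919e-06,3.372564954785e+04,6
N,1.175338040980e-01,3.500000000000e-02,7
N,2.030778891051e-02,7.525000000000e-02,7
N,4.303979586690e+00,7.478627187500e-01,7
N,7.364936039487e-01,1.607904845312e+00,7
N,6.992806513314e-01,1.597996131703e+01,7
N,7.071084144413e-01,3.435691683162e+01,7
N,2.946752836120e-01,7.386737118798e+01,7
N,9.185675601907e-02,1.588148480542e+02,7
N,2.189880505297e-02,3.414519233165e+02,7
N,5.392306012317e-03,7.341216351304e+02,7
N,1.150867523229e-03,1.578361515530e+03,7
N,2.409116203529e-04,3.393477258390e+03,7
N,7.276590356809e-05,7.295976105539e+03,7
N,1.890265195011e-06,1.568634862691e+04,7
N,6.564570880522e-06,3.372564954785e+04,7
O,3.414725428458e+00,7.478627187500e-01,8
O,2.794126536523e+00,1.607904845312e+00,8
O,3.280856163632e-01,1.597996131703e+01,8
O,8.676502422354e-01,3.435691683162e+01,8
O,3.966503122779e-01,7.386737118798e+01,8
O,1.526774614099e-01,1.588148480542e+02,8
O,3.383719261517e-02,3.414519233165e+02,8
O,9.903653270898e-03,7.341216351304e+02,8
O,1.735353904156e-03,1.578361515530e+03,8
O,4.828417479574e-04,3.393477258390e+03,8
O,1.074294674328e-04,7.295976105539e+03,8
O,7.069896344495e-06,1.568634862691e+04,8
O,1.086183131649e-05,3.372564954785e+04,8
F,4.110197923042e-01,3.478431250000e-01,9
F,7.805713371760e-01,7.478627187500e-01,9
F,5.858920856128e+00,1.607904845312e+00,9
F,1.747683793566e-01,3.456995417422e+00,9
F,8.473409575510e-02,1.597996131703e+01,9
F,8.534547802901e-01,3.435691683162e+01,9
F,5.453393773250e-01,7.386737118798e+01,9
F,2.156584660981e-01,1.588148480542e+02,9
F,5.680378872189e-02,3.414519233165e+02,9
F,1.460524714590e-02,7.341216351304e+02,9
F,3.224113821580e-03,1.578361515530e+03,9
F,6.686143736467e-04,3.393477258390e+03,9
F,2.076421024915e-04,7.295976105539e+03,9
F,4.858474967560e-06,1.568634862691e+04,9
F,1.865092616776e-05,3.372564954785e+04,9
Mg,1.071027846131e+00,7.525000000000e-02,12
Mg,1.140601155248e+00,1.617875000000e-01,12
Mg,4.374418709141e-01,7.478627187500e-01,12
Mg,6.684088974026e+00,3.456995417422e+00,12
Mg,9.952446672122e-01,7.432540147457e+00,12
Mg,1.647760363152e-01,3.435691683162e+01,12
Mg,8.512090734755e-01,7.386737118798e+01,12
Mg,4.365547092132e-01,1.588148480542e+02,12
Mg,1.662130786552e-01,3.414519233165e+02,12
Mg,3.899190350762e-02,7.341216351304e+02,12
Mg,1.128948520522e-02,1.578361515530e+03,12
Mg,1.750867554733e-03,3.393477258390e+03,12
Mg,7.488311133000e-04,7.295976105539e+03,12
Mg,6.150142958886e-05,3.372564954785e+04,12
S,5.479531506890e+00,3.478431250000e-01,16
S,1.359420109746e+00,7.478627187500e-01,16
S,6.524756571784e+00,7.432540147457e+00,16
S,9.957378489356e-01,1.597996131703e+01,16
S,3.403652853173e-01,7.386737118798e+01,16
S,7.914859776870e-01,1.588148480542e+02,16
S,3.492099416693e-01,3.414519233165e+02,16
S,1.209910583941e-01,7.341216351304e+02,16
S,2.957446021956e-02,1.578361515530e+03,16
S,6.606428024018e-03,3.393477258390e+03,16
S,2.078425674635e-03,7.295976105539e+03,16
S,5.151598672429e-05,1.568634862691e+04,16
S,1.908696716643e-04,3.372564954785e+04,16
Cl,6.381144268325e+00,3.478431250000e-01,17
Cl,1.627867515522e+00,7.478627187500e-01,17
Cl,5.274131542752e+00,7.432540147457e+00,17
Cl,2.180950206745e+00,1.597996131703e+01,17
Cl,1.646854286824e-01,7.386737118798e+01,17
Cl,7.955549778150e-01,1.588148480542e+02,17
Cl,3.871131095489e-01,3.414519233165e+02,17
Cl,1.422695792654e-01,7.341216351304e+02,17
Cl,3.541997743407e-02,1.578361515530e+03,17
Cl,8.035364823131e-03,3.393477258390e+03,17
Cl,2.530746545869e-03,7.295976105539e+03,17
Cl,6.378977363257e-05,1.568634862691e+04,17
Cl,2.334927676561e-04,3.372564954785e+04,17
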