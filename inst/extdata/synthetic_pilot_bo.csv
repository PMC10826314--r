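"temperature","time","ratio","yield","kappa","viscosity"
140,60,5,53.9331875791768,39.2940025235156,786.11590132524
120,120,10,56.0263888575213,36.9769900088932,845.166551097362
160,120,10,50.0005666704645,5.43298530201568,367.956974832682
140,180,10,50.7952918462224,4.57947142494331,454.319116449145
140,120,7.5,53.7313888804273,18.2136462937325,620.545829825565
143.105906790386,168.823239169264,9.13527058004282,50.3421302770256,4.54872102397734,445.464148635267
147.491040933176,180,10,49.1710881285687,3.32244701443907,378.860084031205
137.913515954525,176.969002158824,8.67422827807408,50.8630828934437,5.30092931952075,510.033466328507
138.884399200735,154.686821257802,9.44022946600206,52.985842081219,8.42023778833599,540.310827843032
143.30697637182,180,6.48524117526454,48.7119575680136,3.65095019784754,419.833157048324
135.013049357589,180,5,50.9124422169713,5.6333772345613,544.054051611348
138.769574683991,160.733103048426,6.81041732923906,52.0535518645005,6.84824442247158,543.098016906109
160,180,5,45.7224636732628,2.46043004351482,327.600628950729
138.587302565958,180,6.46999850015194,49.8899723058359,4.58484739948097,492.87223830297
140.389732153779,162.325317057877,8.5723669499797,51.2486336890879,6.29013472488791,496.643682831895
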