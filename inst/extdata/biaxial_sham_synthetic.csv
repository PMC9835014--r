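"stretch","stress_pa"
1,0
1.005,255.237
1.01,506.744
1.015,754.641
1.02,999.047
1.025,1248.626
1.03,1546.24
1.035,1943.295
1.04,2491.189
1.045,3241.311
1.05,4245.033
1.055,5553.718
1.06,7218.708
1.065,9294.602
1.07,11849.065
1.075,14953.013
1.08,18677.339
1.085,23078.77
1.09,28157.48
1.095,33899.48
1.1,40290.751
1.105,47317.248
1.11,54964.901
1.115,63219.615
1.12,72067.268
1.125,81493.719
1.13,91484.803
1.135,102026.334
1.14,113104.107
1.145,124703.898
1.15,136811.465
1.155,149412.546
1.16,162492.867
1.165,176043.774
1.17,190079.155
1.175,204613.049
1.18,219637.584
1.185,235139.402
1.19,251105.129
1.195,267521.38
1.2,284374.754
1.205,301651.841
1.21,319339.219
1.215,337423.455
1.22,355891.106
1.225,374728.721
1.23,393922.838
1.235,413459.989
1.24,433326.697
1.245,453509.48
1.25,473994.848
1.255,494769.306
1.26,515819.352
1.265,537131.482
1.27,558692.187
1.275,580487.952
1.28,602505.262
1.285,624730.596
1.29,647150.434
1.295,669751.253
1.3,692519.526
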