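sex,age_months,metric,L,M,S
M,24,height_for_age,1,93.155,0.04242
M,30,height_for_age,1,95.596,0.04253
M,36,height_for_age,1,97.949,0.04263
M,42,height_for_age,1,100.233,0.04274
M,48,height_for_age,1,102.459,0.04284
M,54,height_for_age,1,104.635,0.04295
M,60,height_for_age,1,106.767,0.04305
M,66,height_for_age,1,108.862,0.04316
M,72,height_for_age,1,110.922,0.04326
M,78,height_for_age,1,112.952,0.04337
M,84,height_for_age,1,114.954,0.04347
M,90,height_for_age,1,116.93,0.04358
M,96,height_for_age,1,118.883,0.04368
M,102,height_for_age,1,120.814,0.04379
M,108,height_for_age,1,122.725,0.04389
M,114,height_for_age,1,124.616,0.044
M,120,height_for_age,1,126.49,0.04411
M,126,height_for_age,1,128.347,0.04421
M,132,height_for_age,1,130.188,0.04432
M,138,height_for_age,1,132.013,0.04442
M,144,height_for_age,1,133.825,0.04453
M,150,height_for_age,1,135.623,0.04463
M,156,height_for_age,1,137.409,0.04474
M,162,height_for_age,1,139.182,0.04484
M,168,height_for_age,1,140.943,0.04495
M,174,height_for_age,1,142.693,0.04505
M,180,height_for_age,1,144.432,0.04516
M,186,height_for_age,1,146.161,0.04526
M,192,height_for_age,1,147.879,0.04537
M,198,height_for_age,1,149.588,0.04547
M,204,height_for_age,1,151.288,0.04558
M,210,height_for_age,1,152.979,0.04568
M,216,height_for_age,1,154.661,0.04579
M,222,height_for_age,1,156.334,0.04589
M,228,height_for_age,1,158,0.046
M,234,height_for_age,1,159.658,0.04611
M,240,height_for_age,1,161.308,0.04621
M,246,height_for_age,1,162.95,0.04632
M,252,height_for_age,1,164.586,0.04642
M,24,bmi_for_age,-1.6,15.247,0.08974
M,30,bmi_for_age,-1.6,15.273,0.09092
M,36,bmi_for_age,-1.6,15.305,0.09211
M,42,bmi_for_age,-1.6,15.343,0.09329
M,48,bmi_for_age,-1.6,15.386,0.09447
M,54,bmi_for_age,-1.6,15.436,0.09566
M,60,bmi_for_age,-1.6,15.491,0.09684
M,66,bmi_for_age,-1.6,15.552,0.09803
M,72,bmi_for_age,-1.6,15.619,0.09921
M,78,bmi_for_age,-1.6,15.692,0.10039
M,84,bmi_for_age,-1.6,15.77,0.10158
M,90,bmi_for_age,-1.6,15.854,0.10276
M,96,bmi_for_age,-1.6,15.945,0.10395
M,102,bmi_for_age,-1.6,16.041,0.10513
M,108,bmi_for_age,-1.6,16.142,0.10632
M,114,bmi_for_age,-1.6,16.25,0.1075
M,120,bmi_for_age,-1.6,16.363,0.10868
M,126,bmi_for_age,-1.6,16.483,0.10987
M,132,bmi_for_age,-1.6,16.608,0.11105
M,138,bmi_for_age,-1.6,16.739,0.11224
M,144,bmi_for_age,-1.6,16.875,0.11342
M,150,bmi_for_age,-1.6,17.018,0.11461
M,156,bmi_for_age,-1.6,17.166,0.11579
M,162,bmi_for_age,-1.6,17.32,0.11697
M,168,bmi_for_age,-1.6,17.48,0.11816
M,174,bmi_for_age,-1.6,17.646,0.11934
M,180,bmi_for_age,-1.6,17.818,0.12053
M,186,bmi_for_age,-1.6,17.995,0.12171
M,192,bmi_for_age,-1.6,18.178,0.12289
M,198,bmi_for_age,-1.6,18.367,0.12408
M,204,bmi_for_age,-1.6,18.562,0.12526
M,210,bmi_for_age,-1.6,18.763,0.12645
M,216,bmi_for_age,-1.6,18.97,0.12763
M,222,bmi_for_age,-1.6,19.182,0.12882
M,228,bmi_for_age,-1.6,19.4,0.13
M,234,bmi_for_age,-1.6,19.624,0.13118
M,240,bmi_for_age,-1.6,19.854,0.13237
M,246,bmi_for_age,-1.6,20.089,0.13355
M,252,bmi_for_age,-1.6,20.331,0.13474
F,24,height_for_age,1,92.155,0.04242
F,30,height_for_age,1,94.596,0.04253
F,36,height_for_age,1,96.949,0.04263
F,42,height_for_age,1,99.233,0.04274
F,48,height_for_age,1,101.459,0.04284
F,54,height_for_age,1,103.635,0.04295
F,60,height_for_age,1,105.767,0.04305
F,66,height_for_age,1,107.862,0.04316
F,72,height_for_age,1,109.922,0.04326
F,78,height_for_age,1,111.952,0.04337
F,84,height_for_age,1,113.954,0.04347
F,90,height_for_age,1,115.93,0.04358
F,96,height_for_age,1,117.883,0.04368
F,102,height_for_age,1,119.814,0.04379
F,108,height_for_age,1,121.725,0.04389
F,114,height_for_age,1,123.616,0.044
F,120,height_for_age,1,125.49,0.04411
F,126,height_for_age,1,127.347,0.04421
F,132,height_for_age,1,129.188,0.04432
F,138,height_for_age,1,131.013,0.04442
F,144,height_for_age,1,132.825,0.04453
F,150,height_for_age,1,134.623,0.04463
F,156,height_for_age,1,136.409,0.04474
F,162,height_for_age,1,138.182,0.04484
F,168,height_for_age,1,139.943,0.04495
F,174,height_for_age,1,141.693,0.04505
F,180,height_for_age,1,143.432,0.04516
F,186,height_for_age,1,145.161,0.04526
F,192,height_for_age,1,146.879,0.04537
F,198,height_for_age,1,148.588,0.04547
F,204,height_for_age,1,150.288,0.04558
F,210,height_for_age,1,151.979,0.04568
F,216,height_for_age,1,153.661,0.04579
F,222,height_for_age,1,155.334,0.04589
F,228,height_for_age,1,157,0.046
F,234,height_for_age,1,158.658,0.04611
F,240,height_for_age,1,160.308,0.04621
F,246,height_for_age,1,161.95,0.04632
F,252,height_for_age,1,163.586,0.04642
F,24,bmi_for_age,-1.6,15.247,0.08974
F,30,bmi_for_age,-1.6,15.273,0.09092
F,36,bmi_for_age,-1.6,15.305,0.09211
F,42,bmi_for_age,-1.6,15.343,0.09329
F,48,bmi_for_age,-1.6,15.386,0.09447
F,54,bmi_for_age,-1.6,15.436,0.09566
F,60,bmi_for_age,-1.6,15.491,0.09684
F,66,bmi_for_age,-1.6,15.552,0.09803
F,72,bmi_for_age,-1.6,15.619,0.09921
F,78,bmi_for_age,-1.6,15.692,0.10039
F,84,bmi_for_age,-1.6,15.77,0.10158
F,90,bmi_for_age,-1.6,15.854,0.10276
F,96,bmi_for_age,-1.6,15.945,0.10395
F,102,bmi_for_age,-1.6,16.041,0.10513
F,108,bmi_for_age,-1.6,16.142,0.10632
F,114,bmi_for_age,-1.6,16.25,0.1075
F,120,bmi_for_age,-1.6,16.363,0.10868
F,126,bmi_for_age,-1.6,16.483,0.10987
F,132,bmi_for_age,-1.6,16.608,0.11105
F,138,bmi_for_age,-1.6,16.739,0.11224
F,144,bmi_for_age,-1.6,16.875,0.11342
F,150,bmi_for_age,-1.6,17.018,0.11461
F,156,bmi_for_age,-1.6,17.166,0.11579
F,162,bmi_for_age,-1.6,17.32,0.11697
F,168,bmi_for_age,-1.6,17.48,0.11816
F,174,bmi_for_age,-1.6,17.646,0.11934
F,180,bmi_for_age,-1.6,17.818,0.12053
F,186,bmi_for_age,-1.6,17.995,0.12171
F,192,bmi_for_age,-1.6,18.178,0.12289
F,198,bmi_for_age,-1.6,18.367,0.12408
F,204,bmi_for_age,-1.6,18.562,0.12526
F,210,bmi_for_age,-1.6,18.763,0.12645
F,216,bmi_for_age,-1.6,18.97,0.12763
F,222,bmi_for_age,-1.6,19.182,0.12882
F,228,bmi_for_age,-1.6,19.4,0.13
F,234,bmi_for_age,-1.6,19.624,0.13118
F,240,bmi_for_age,-1.6,19.854,0.13237
F,246,bmi_for_age,-1.6,20.089,0.13355
F,252,bmi_for_age,-1.6,20.331,0.13474
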