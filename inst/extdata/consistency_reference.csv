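case,flute,violin,horns,piano,oboe,total,mean
562,13.28,16.58,19.67,7.16,8.77,65.46,13.092
581,10.95,8.57,8.61,6.78,21.64,56.55,11.31
584,55.43,50.73,4.9,50.26,33.89,195.21,39.042
590,2.22,79.3,35.21,40.63,20.55,177.91,35.582
594,48.48,2.42,6.39,10.33,1.66,69.28,13.856
596,8.00,9.33,6.61,14.41,58.44,96.79,19.358
599,31.61,8.36,38.15,46.21,5.43,129.76,25.952
601,8.37,3.92,15.43,14.52,25.71,67.95,13.59
604,38.95,12.39,3.35,5,0.93,60.62,12.124
609,0.35,16.06,NaN,0.86,25.71,42.98,10.745
614,31.59,52.72,22.86,3.29,17.6,128.06,25.612
617,15.11,33.96,8.77,10.42,5.06,73.32,14.664
621,47.14,33.22,33.37,17.62,56.15,187.5,37.5
623,23.67,62.1,23.55,7.53,42.96,159.81,31.962
624,41.11,78.57,52.68,15.01,72.79,260.16,52.032
626,26.92,11.88,8.65,2.19,5.09,54.73,10.946
629,8.86,3.9,12.85,2.86,12.69,41.16,8.232
635,13.26,47.37,46.32,5.05,41.64,153.64,30.728
640,5.79,10.58,8.97,0.96,10.18,36.48,7.296
643,1.31,48.32,5.78,40.3,8.33,104.04,20.808
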