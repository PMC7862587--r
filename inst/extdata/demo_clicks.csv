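participant_id,recording_id,repetition,time_s
P01,tori,1,11.702
P01,tori,1,28.912
P01,tori,1,44.767
P01,tori,1,77.974
P01,tori,1,97.665
P01,tori,1,114.267
P01,tori,1,132.352
P01,tori,1,173.254
P01,tori,1,192.135
P01,tori,1,210.055
P01,tori,1,218.203
P01,tori,1,222.721
P01,tori,1,232.384
P01,tori,1,240.388
P01,tori,1,253.367
P01,tori,1,299.038
P01,tori,1,308.389
P01,tori,2,11.651
P01,tori,2,49.777
P01,tori,2,58.782
P01,tori,2,93.932
P01,tori,2,115.052
P01,tori,2,148.405
P01,tori,2,154.333
P01,tori,2,174.138
P01,tori,2,193.798
P01,tori,2,220.676
P01,tori,2,224.811
P01,tori,2,256.181
P01,tori,2,281.601
P01,tori,2,308.226
P02,tori,1,9.347
P02,tori,1,10.763
P02,tori,1,43.24
P02,tori,1,58.473
P02,tori,1,77.259
P02,tori,1,93.812
P02,tori,1,109.819
P02,tori,1,112.974
P02,tori,1,134.151
P02,tori,1,148.668
P02,tori,1,153.282
P02,tori,1,161.323
P02,tori,1,175.206
P02,tori,1,192.892
P02,tori,1,200.66
P02,tori,1,211.409
P02,tori,1,216.037
P02,tori,1,236.757
P02,tori,1,265.315
P02,tori,1,274.645
P02,tori,1,277.271
P02,tori,1,292.11
P02,tori,1,305.092
P02,tori,1,315.067
P02,tori,2,11.399
P02,tori,2,17.842
P02,tori,2,29.257
P02,tori,2,30.848
P02,tori,2,32.436
P02,tori,2,42.085
P02,tori,2,55.794
P02,tori,2,57.331
P02,tori,2,60.411
P02,tori,2,62.659
P02,tori,2,80.305
P02,tori,2,95.568
P02,tori,2,107.236
P02,tori,2,133.32
P02,tori,2,143.734
P02,tori,2,147.176
P02,tori,2,149.377
P02,tori,2,158.752
P02,tori,2,173.207
P02,tori,2,194.124
P02,tori,2,204.701
P02,tori,2,209.523
P02,tori,2,211.405
P02,tori,2,218.346
P02,tori,2,231.645
P02,tori,2,242.23
P02,tori,2,255.129
P02,tori,2,260.355
P02,tori,2,274.238
P02,tori,2,293.245
P02,tori,2,308.282
P03,tori,1,45.893
P03,tori,1,58.896
P03,tori,1,131.575
P03,tori,1,134.793
P03,tori,1,147.716
P03,tori,1,158.866
P03,tori,1,165.91
P03,tori,1,177.098
P03,tori,1,210.415
P03,tori,1,228.17
P03,tori,1,241.284
P03,tori,1,257.809
P03,tori,2,3.577
P03,tori,2,52.601
P03,tori,2,60.521
P03,tori,2,131.663
P03,tori,2,132.464
P03,tori,2,174.171
P03,tori,2,187.251
P03,tori,2,210.286
P03,tori,2,215.827
P03,tori,2,222.036
P03,tori,2,238.896
P03,tori,2,274.55
P03,tori,2,291.699
P03,tori,2,313.801
P04,tori,1,12.019
P04,tori,1,16.052
P04,tori,1,18.645
P04,tori,1,29.119
P04,tori,1,33.382
P04,tori,1,42.42
P04,tori,1,70.932
P04,tori,1,75.327
P04,tori,1,100.912
P04,tori,1,108.496
P04,tori,1,110.764
P04,tori,1,116.042
P04,tori,1,126.377
P04,tori,1,130.506
P04,tori,1,131.937
P04,tori,1,134.348
P04,tori,1,167.734
P04,tori,1,175.361
P04,tori,1,220.572
P04,tori,1,226.582
P04,tori,1,238.858
P04,tori,1,246.209
P04,tori,1,255.052
P04,tori,1,270.42
P04,tori,1,274.186
P04,tori,1,279.534
P04,tori,1,285.752
P04,tori,1,293.921
P04,tori,1,306.967
P04,tori,1,315.836
P04,tori,2,4.692
P04,tori,2,12.027
P04,tori,2,14.749
P04,tori,2,19.714
P04,tori,2,28.175
P04,tori,2,42.042
P04,tori,2,60.579
P04,tori,2,72.658
P04,tori,2,78.948
P04,tori,2,95.962
P04,tori,2,127.749
P04,tori,2,130.738
P04,tori,2,142.599
P04,tori,2,171.111
P04,tori,2,171.254
P04,tori,2,174.774
P04,tori,2,179.652
P04,tori,2,182.305
P04,tori,2,194.366
P04,tori,2,233.343
P04,tori,2,251.098
P04,tori,2,257.52
P04,tori,2,263.931
P04,tori,2,286.494
P04,tori,2,293.06
P04,tori,2,301.361
P05,tori,1,10.765
P05,tori,1,28.407
P05,tori,1,43.498
P05,tori,1,51.705
P05,tori,1,58.946
P05,tori,1,65.223
P05,tori,1,78.965
P05,tori,1,96.842
P05,tori,1,112.876
P05,tori,1,156.725
P05,tori,1,179.973
P05,tori,1,193.155
P05,tori,1,197.099
P05,tori,1,210.042
P05,tori,1,221.805
P05,tori,1,245.413
P05,tori,1,256.028
P05,tori,1,274.763
P05,tori,1,304.654
P05,tori,2,10.94
P05,tori,2,26.598
P05,tori,2,33.265
P05,tori,2,35.227
P05,tori,2,44.811
P05,tori,2,77.797
P05,tori,2,86.81
P05,tori,2,93.933
P05,tori,2,104.167
P05,tori,2,115.595
P05,tori,2,120.105
P05,tori,2,134.01
P05,tori,2,148.863
P05,tori,2,159.477
P05,tori,2,175.779
P05,tori,2,179.372
P05,tori,2,192.57
P05,tori,2,211.057
P05,tori,2,215.23
P05,tori,2,222.24
P05,tori,2,235.216
P05,tori,2,238.031
P05,tori,2,257.102
P05,tori,2,264.066
P05,tori,2,272.011
P05,tori,2,272.626
P05,tori,2,281.627
P05,tori,2,290.189
P05,tori,2,305.424
P06,tori,1,10.925
P06,tori,1,27.445
P06,tori,1,44.965
P06,tori,1,58.213
P06,tori,1,63.847
P06,tori,1,75.925
P06,tori,1,94.715
P06,tori,1,135.134
P06,tori,1,148.733
P06,tori,1,210.575
P06,tori,1,220.8
P06,tori,1,233.516
P06,tori,1,240.433
P06,tori,1,275.379
P06,tori,2,10.367
P06,tori,2,24.742
P06,tori,2,42.921
P06,tori,2,60.604
P06,tori,2,75.722
P06,tori,2,82.6
P06,tori,2,113.548
P06,tori,2,128.4
P06,tori,2,134.517
P06,tori,2,149.066
P06,tori,2,174.893
P06,tori,2,193.684
P06,tori,2,210.952
P06,tori,2,221.257
P06,tori,2,237.741
P06,tori,2,256.583
P06,tori,2,273.714
P06,tori,2,281.976
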