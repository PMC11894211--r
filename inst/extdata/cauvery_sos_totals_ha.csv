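year,date,area_ha
2017-18,2017-08-21,1023
2017-18,2017-09-02,27783
2017-18,2017-09-14,10017
2017-18,2017-09-26,59413
2017-18,2017-10-08,45041
2017-18,2017-10-20,63734
2017-18,2017-11-01,165982
2017-18,2017-11-13,62296
2017-18,2017-11-25,32479
2017-18,2017-12-07,22479
2017-18,2017-12-19,15242
2017-18,2017-12-31,2569
2017-18,2018-01-12,523
2018-19,2018-08-16,42573
2018-19,2018-08-28,26737
2018-19,2018-09-09,45637
2018-19,2018-09-21,103090
2018-19,2018-10-03,110077
2018-19,2018-10-27,99165
2018-19,2018-11-08,20011
2018-19,2018-11-20,3594
2018-19,2018-12-02,4154
2018-19,2018-12-14,1563
2019-20,2019-08-23,28496
2019-20,2019-09-04,14383
2019-20,2019-09-16,26916
2019-20,2019-09-28,64760
2019-20,2019-10-10,110579
2019-20,2019-10-22,130936
2019-20,2019-11-03,33269
2019-20,2019-11-15,63730
2019-20,2019-11-27,19862
2019-20,2019-12-09,13425
2019-20,2020-01-02,487
2020-21,2020-08-05,14285
2020-21,2020-08-17,4646
2020-21,2020-08-29,9827
2020-21,2020-09-10,21097
2020-21,2020-09-22,78854
2020-21,2020-10-04,101900
2020-21,2020-10-16,133698
2020-21,2020-10-28,78582
2020-21,2020-11-09,51515
2020-21,2020-11-21,5352
2020-21,2020-12-03,8462
2020-21,2020-12-15,3495
2021-22,2021-08-12,66230
2021-22,2021-08-24,30795
2021-22,2021-09-05,33455
2021-22,2021-09-17,33202
2021-22,2021-09-29,83155
2021-22,2021-10-11,98517
2021-22,2021-10-23,60513
2021-22,2021-11-04,103173
2021-22,2021-11-16,8483
2021-22,2021-11-28,7200
2022-23,2022-08-19,30183
2022-23,2022-08-31,2526
2022-23,2022-09-12,9827
2022-23,2022-09-24,49237
2022-23,2022-10-06,74797
2022-23,2022-10-30,133779
2022-23,2022-11-11,102240
2022-23,2022-11-23,46199
2022-23,2022-12-05,25304
2022-23,2022-12-17,2493
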