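district,year,area_ha
Thanjavur,2017-18,126226
Thiruvarur,2017-18,132258
Nagapattinam,2017-18,119411
Cuddalore,2017-18,99170
Tiruchirapalli,2017-18,31516
Thanjavur,2018-19,124618
Thiruvarur,2018-19,126019
Nagapattinam,2018-19,105107
Cuddalore,2018-19,77312
Tiruchirapalli,2018-19,23545
Thanjavur,2019-20,141287
Thiruvarur,2019-20,125589
Nagapattinam,2019-20,117761
Cuddalore,2019-20,104331
Tiruchirapalli,2019-20,17877
Thanjavur,2020-21,141077
Thiruvarur,2020-21,127752
Nagapattinam,2020-21,110938
Cuddalore,2020-21,88002
Tiruchirapalli,2020-21,43944
Thanjavur,2021-22,139171
Thiruvarur,2021-22,127028
Nagapattinam,2021-22,124219
Cuddalore,2021-22,101821
Tiruchirapalli,2021-22,32484
Thanjavur,2022-23,117907
Thiruvarur,2022-23,110512
Nagapattinam,2022-23,102792
Cuddalore,2022-23,100348
Tiruchirapalli,2022-23,45027
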