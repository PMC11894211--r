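year,date,district,area_ha
2017-18,2017-11-01,Thanjavur,25024
2017-18,2017-11-01,Thiruvarur,55370
2017-18,2017-11-01,Nagapattinam,52499
2017-18,2017-11-01,Cuddalore,30784
2017-18,2017-11-01,Tiruchirapalli,2305
2020-21,2020-10-16,Thanjavur,36509
2020-21,2020-10-16,Thiruvarur,31604
2020-21,2020-10-16,Nagapattinam,28823
2020-21,2020-10-16,Cuddalore,15213
2020-21,2020-10-16,Tiruchirapalli,21549
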