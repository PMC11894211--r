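year,bin,start,end
2017-18,early,2017-08-21,2017-09-14
2017-18,major,2017-09-26,2017-11-13
2017-18,late,2017-11-25,2018-01-12
2018-19,early,2018-08-16,2018-08-28
2018-19,major,2018-09-09,2018-11-08
2018-19,late,2018-11-20,2018-12-14
2019-20,early,2019-08-23,2019-09-16
2019-20,major,2019-09-28,2019-11-15
2019-20,late,2019-11-27,2020-01-02
2020-21,early,2020-08-05,2020-09-10
2020-21,major,2020-09-22,2020-11-09
2020-21,late,2020-11-21,2020-12-15
2021-22,early,2021-08-12,2021-09-17
2021-22,major,2021-09-29,2021-11-04
2021-22,late,2021-11-16,2021-11-28
2022-23,early,2022-08-19,2022-09-12
2022-23,major,2022-09-24,2022-11-23
2022-23,late,2022-12-05,2022-12-17
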