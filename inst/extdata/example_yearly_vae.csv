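year,events,device_days
2008,94,4251
2009,71,4100
2010,60,4223
2011,67,4634
2012,58,4303
2013,69,4582
2014,70,4333
2015,77,4430
2016,26,2365
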