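race,year,rate,lower,upper
AIAN,2000,9.0,7.9,10.2
Asian,2000,11.1,10.6,11.6
Black,2000,11.8,11.5,12.1
Latino,2000,9.1,8.8,9.5
White,2000,5.5,5.5,5.6
Total,2000,6.5,6.4,6.6
AIAN,2019,6.2,5.4,7.0
Asian,2019,5.7,5.5,6.0
Black,2019,6.8,6.6,7.0
Latino,2019,5.9,5.7,6.1
White,2019,3.5,3.4,3.6
Total,2019,4.2,4.2,4.3
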