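race,reference,n_total,n_higher,n_significant
AIAN,White,465,377,294
Latino,White,1469,1295,930
Asian,White,667,663,558
Black,White,1486,1484,1403
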