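                 0,0.89910331328303439,                 0,0.19460560862210202,0.72475888064826322,                 0,                 0,2.4788005933633146
1.4992276656316978,                 0,0.81378069727712987,                 0,                 0,0.10359641167836318,                 0,                 0
                 0,0.4078689454791351,                 0,                 0,                 0,                 0,                 0,                 0
0.60043161974298676,0.57499890381574426,1.2017502614990667,                 0,                 0,                 0,                 0,                 0
0.63880479273110291,0.11048706402314827,0.42616464650643487,                 0,                 0,0.26571717568317599,                 0,1.1993387041281485
2.3055798164766141,                 0,                 0,1.3921712640672723,                 0,                 0,1.3500197645304526,                 0
                 0,                 0,                 0,                 0,                 0,                 0,                 0,2.8127938708128135
                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0
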