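                 0,15.407003845259084,10.486512069676843,21.126816331622265,22.245710687780456,38.201787550129609,29.153886983041268,38.667659918180561
15.407003845259084,                 0,18.534274084673964,29.946197337850215,33.821034705892423,51.424719449733153,44.492884244451695, 45.05989608120737
10.486512069676843,18.534274084673964,                 0,12.478357180662611,31.324179989553148, 45.30008284765286,31.126724293113408,48.601104071620085
21.126816331622265,29.946197337850215,12.478357180662611,                 0,37.945785176862785, 48.43602885346364,29.355884397351144, 57.46941831272035
22.245710687780456,33.821034705892423,31.324179989553148,37.945785176862785,                 0, 18.07151345797994,23.848133448856338,21.217601854714058
38.201787550129609,51.424719449733153, 45.30008284765286, 48.43602885346364, 18.07151345797994,                 0,22.847739610218966,27.139073790725011
29.153886983041268,44.492884244451695,31.126724293113408,29.355884397351144,23.848133448856338,22.847739610218966,                 0, 43.00349694373952
38.667659918180561, 45.05989608120737,48.601104071620085, 57.46941831272035,21.217601854714058,27.139073790725011, 43.00349694373952,                 0
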