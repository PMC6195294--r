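"segment","key","baseline_value","tracks_dim"
"manus","b",0.126126,"length"
"manus","c",0.184144,"radius"
"antebrachium","b",0.26162,"length"
"antebrachium","c",0.141465,"radius_dist"
"brachium","b",0.24725,"length"
"brachium","c",0.339565,"radius_prox"
"brachium","d",0.18335,"radius_dist"
"pes","b",0.26624,"length"
"pes","c",0.070937,"base_x"
"pes","d",0.023051,"base_y"
"crus","b",0.24355,"length"
"crus","c",0.187008,"radius_dist"
"thigh","b",0.26409,"length"
"thigh","c",0.247207,"radius_dist"
"tail","b",0.47101,"length"
"tail","c",0.147075,"radius"
"head","b",0.32153,"semi_z"
"head","c",0.104544,"semi_x"
"neck","b",0.26167,"length"
"neck","c",0.333393,"radius_prox"
"neck","d",0.375065,"radius_dist"
"neck","e",0.416738,"radius_dist"
"abdomen","c",0.39313,"length"
"abdomen","b",0.692443,"radius_prox"
"abdomen","d",0.553955,"radius_dist"
"thorax","c",0.46262,"length"
"thorax","d",0.648956,"radius_dist"
"thorax","b",0.551616,"radius_prox"
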