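"segment","endpoints","mass_fraction","mass_fraction_sd","com_prox","com_prox_sd","com_dist","com_dist_sd","density_kg_m3","density_sd","volume_cm3","volume_sd","length_ref_m"
"manus","mid carpus to distal 3rd phalanx",0.0072,2e-04,0.4848,0.0089,0.5185,0.0091,934.02,18.1,287,12.9,0.21021
"antebrachium","lateral epicondyle to carpal joint",0.0138,5e-04,0.3941,0.0055,0.6076,0.0053,977.54,17.1,521,30.7,0.26162
"brachium","glenohumeral joint to lateral epicondyle",0.024,0.0013,0.4183,0.0183,0.5869,0.0197,974.37,12.71,908,86.2,0.24725
"pes","tuber calcaneus to distal 3rd phalanx",0.0082,2e-04,0.514,0.0044,0.488,0.0042,1013.58,12.45,305,12.6,0.26624
"crus","femoral condyle to lateral malleolus",0.015,6e-04,0.3659,0.0113,0.6364,0.0111,1010.6,19.38,548,33.3,0.24355
"thigh","greater trochanter to femoral condyle",0.0451,0.0028,0.4463,0.0115,0.5601,0.0124,939.78,13.4,1760,183,0.26409
"head","inion to prosthion",0.077,0.0039,0.3165,0.0081,0.6842,0.0082,1004.18,20.29,1000,20.3,0.32153
"neck","atlas/axis to C7/T1",0.0661,0.0068,0.5627,0.0122,0.4431,0.0128,970.01,25.53,2550,292,0.26167
"abdomen","T13/L1 to tail base",0.2415,0.0153,0.4677,0.0047,0.5343,0.005,963.89,7.71,9260,714,0.39313
"thorax","C7/T1 to T13/L1",0.3806,0.0101,0.5368,0.011,0.467,0.0109,1083.39,83.44,13300,1070,0.46262
"tail","base of tail to tip",0.008,5e-04,0.3128,0.0158,0.6892,0.0162,900.63,63.73,345,45.1,0.47101
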