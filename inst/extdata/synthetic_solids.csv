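"segment","shape","dim_name","dim_value"
"manus","cylinder","radius",0.020726
"manus","cylinder","length",0.21021
"antebrachium","conical_frustum","radius_prox",0.027877
"antebrachium","conical_frustum","radius_dist",0.022302
"antebrachium","conical_frustum","length",0.26162
"brachium","conical_frustum","radius_prox",0.038908
"brachium","conical_frustum","radius_dist",0.029181
"brachium","conical_frustum","length",0.24725
"pes","rectangular_pyramid","base_x",0.070937
"pes","rectangular_pyramid","base_y",0.047291
"pes","rectangular_pyramid","length",0.26624
"crus","conical_frustum","radius_prox",0.030432
"crus","conical_frustum","radius_dist",0.022824
"crus","conical_frustum","length",0.24355
"thigh","conical_frustum","radius_prox",0.052549
"thigh","conical_frustum","radius_dist",0.039412
"thigh","conical_frustum","length",0.26409
"head","ellipsoid","semi_x",0.064733
"head","ellipsoid","semi_y",0.064733
"head","ellipsoid","semi_z",0.160765
"neck","conical_frustum","radius_prox",0.048994
"neck","conical_frustum","radius_dist",0.061242
"neck","conical_frustum","length",0.26167
"abdomen","conical_frustum","radius_prox",0.095806
"abdomen","conical_frustum","radius_dist",0.076645
"abdomen","conical_frustum","length",0.39313
"thorax","conical_frustum","radius_prox",0.086573
"thorax","conical_frustum","radius_dist",0.10185
"thorax","conical_frustum","length",0.46262
"tail","cone","radius",0.025743
"tail","cone","length",0.47101
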