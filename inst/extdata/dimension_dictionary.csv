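"segment","key","definition","ambiguous"
"all","a","whole body mass (kg)",0
"manus","b","length of caudal edge of metacarpal pad to podactylion III (m)",0
"manus","c","bistyloidal circumference at carpal joint (m)",0
"antebrachium","b","length of antebrachium, proximal to distal joint centers (m)",0
"antebrachium","c","bistyloidal circumference at carpal joint (m)",0
"brachium","b","length of brachium, proximal to distal joint centers (m)",0
"brachium","c","circumference at highest point in the axilla, perpendicular to long axis (m)",0
"brachium","d","circumference at olecranon process across epicondyles (m)",0
"pes","b","length of proximal joint center to podactylion III (m)",0
"pes","c","breadth across metatarsal phalangeal joints (m)",0
"pes","d","depth of pes at midpoint between malleoli and base of the pes (m)",0
"crus","b","length of crus, proximal to distal joint centers (m)",0
"crus","c","circumference of hock at malleoli (m)",0
"thigh","b","mid centroid of femoral head (m); far endpoint unstated",1
"thigh","c","circumference of stifle joint at mid-patella (m)",0
"head","b","length of head, atlas/axis joint center to end of nose (m)",0
"head","c","ecto-orbitale breadth (m)",0
"neck","b","length from axis (base of the head) to C7 (m)",0
"neck","c","circumference at axis/atlas joint (base of head) (m)",0
"neck","d","circumference at mid length, halfway between the axis and C7 (m)",0
"neck","e","circumference at C7/T1 (base of neck/shoulders) (m)",0
"abdomen","b","circumference at T13/L1 joint (base of ribs) (m)",0
"abdomen","c","length of T13/L1 to L7/S1 (spinous processes) (m)",0
"abdomen","d","circumference at level of waist (narrowest point) (m)",0
"thorax","b","circumference at C7/T1 (base of neck/shoulders) (m)",0
"thorax","c","length of C7/T1 joint center to T13/L1 joint center (m)",0
"thorax","d","circumference at T13/L1 joint (base of ribs) (m)",0
"tail","b","length from sacrum to tip of tail (m)",0
"tail","c","circumference at sacrum (m)",0
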