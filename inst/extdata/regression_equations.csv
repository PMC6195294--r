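"segment","quantity","axis","coef_a","coef_geom","intercept","term_kind","keys","geom_includes_a","r_squared","note"
"manus","mass","",-0.003,69.762,0.077,"cylinder_volume","b;c",0,0.867,""
"manus","I_xx","int_ext",-0.00012,NA,0.0052,"mass_only","",0,0.721,""
"manus","I_yy","flx_ext",-0.00015,NA,0.00654,"mass_only","",0,0.689,""
"manus","I_zz","abd_add",0.00018,NA,-0.00558,"mass_only","",0,0.87,""
"antebrachium","mass","",0.012,101.084,-0.463,"cylinder_volume","b;c",0,0.903,""
"antebrachium","I_xx","abd_add",-0.00032,0.00066,0.01406,"transverse_cylinder","c;b",1,0.595,""
"antebrachium","I_yy","flx_ext",-5e-05,0.0016,0.00168,"transverse_cylinder","c;b",1,0.459,""
"antebrachium","I_zz","int_ext",1e-04,0.00173,-0.00496,"dim_squared","b",1,0.886,""
"brachium","mass","",0.092,25.062,-3.811,"frustum_volume","b;c;d",0,0.646,""
"brachium","I_xx","abd_add",0.00053,0.00223,-0.199,"transverse_cylinder_circ","c;b",1,0.883,"intercept -0.1990 transcribed as printed"
"brachium","I_yy","flx_ext",0.00082,0.00465,-0.03308,"transverse_cylinder_circ","c;b",1,0.728,""
"brachium","I_zz","int_ext",0.00015,0.003,-0.02139,"axial_frustum","c;d",1,0.408,"intercept printed as 00.02139"
"pes","mass","",-0.009,633.875,0.357,"box_volume","b;c;d",0,0.895,""
"pes","I_xx","abd_add",9e-05,NA,-0.00256,"mass_only","",0,0.87,""
"pes","I_yy","flx_ext",-7e-05,NA,0.00417,"mass_only","",0,0.687,""
"pes","I_zz","int_ext",-0.00016,NA,0.00786,"mass_only","",0,0.594,""
"crus","mass","",0.075,139.127,-3.393,"cylinder_volume","b;c",0,0.576,""
"crus","I_xx","abd_add",0.00023,0.00137,-0.00785,"transverse_cylinder","c;b",1,0.903,""
"crus","I_yy","flx_ext",0.00021,0.00108,-0.00659,"transverse_cylinder","c;b",1,0.985,""
"crus","I_zz","int_ext",9e-05,-0.00423,0.00454,"dim_squared","c",1,0.941,""
"thigh","mass","",0.018,105.849,-0.711,"cylinder_volume","b;c",0,0.709,""
"thigh","I_xx","abd_add",-0.00091,0.00258,0.03813,"transverse_cylinder","c;b",1,0.732,""
"thigh","I_yy","flx_ext",-6e-04,0.00536,0.02502,"transverse_cylinder","c;b",1,0.792,"a-coefficient printed as -00.0006a"
"thigh","I_zz","int_ext",-0.00067,1e-05,0.03467,"dim_squared","c",1,0.466,""
"head","mass","",0.243,1602.163,-11.739,"cylinder_volume","b;c",0,0.778,""
"head","I_xx","int_ext",8e-04,0.15568,-0.0916,"dim_squared","c",1,0.984,""
"head","I_yy","flx_ext",-0.00112,-0.00283,0.07403,"ellipsoid_sum","b;c",1,0.72,"a-coefficient printed as -00.00112a"
"head","I_zz","abd_add",-7e-05,-0.00613,0.04484,"ellipsoid_sum","b;c",1,0.708,""
"neck","mass","",0.063,98.915,-3.527,"cylinder_volume","b;d",0,0.952,""
"neck","I_xx","int_ext",-0.00154,-0.00313,0.11749,"axial_frustum","e;c",1,0.816,""
"neck","I_yy","flx_ext",-7e-04,0.01245,0.01634,"transverse_cylinder_circ","e;b",1,0.871,"a-coefficient printed as -00.0007a"
"neck","I_zz","abd_add",-0.00129,0.00719,0.04938,"transverse_cylinder_circ","e;b",1,0.976,""
"abdomen","mass","",0.03,16.692,0.106,"frustum_volume","c;b;d",0,0.957,""
"abdomen","I_xx","int_ext",0.00814,0.00471,-0.28462,"axial_frustum","b;d",1,0.929,""
"abdomen","I_yy","flx_ext",0.01457,0.01824,-0.50031,"transverse_cylinder_circ","b;c",1,0.653,"a-coefficient printed as 00.01457a"
"abdomen","I_zz","abd_add",-0.02726,0.00616,10.08268,"transverse_cylinder_circ","b;c",1,0.687,"intercept +10.08268 transcribed as printed (likely misprint)"
"thorax","mass","",0.094,11.135,4.966,"frustum_volume","c;d;b",0,0.978,""
"thorax","I_xx","int_ext",0.00384,0.00183,-0.05972,"axial_frustum","d;b",1,0.935,""
"thorax","I_yy","flx_ext",-0.00514,0.04659,0.12633,"transverse_cylinder_circ","d;c",1,0.739,"a-coefficient printed as -00.00514a"
"thorax","I_zz","abd_add",-0.00566,0.04428,0.16146,"transverse_cylinder_circ","d;c",1,0.763,""
"tail","mass","",0.02,22.123,-0.667,"cylinder_volume","b;c",0,0.934,""
"tail","I_xx","abd_add",0.00015,0.00198,-0.01353,"transverse_cylinder_circ","c;b",1,0.944,""
"tail","I_yy","flx_ext",-0.00042,0.00148,0.00989,"transverse_cylinder_circ","c;b",1,0.96,""
"tail","I_zz","int_ext",1e-04,0.00173,-0.0041,"dim_squared","c",1,0.913,""
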