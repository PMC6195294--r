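# moments and products of inertia stored in units of 1e-4 kg m^2
"segment","I_int_ext","I_int_ext_sd","I_abd_add","I_abd_add_sd","I_flx_ext","I_flx_ext_sd","P_xy","P_xy_sd","P_xz","P_xz_sd","P_yz","P_yz_sd","axis_xx","axis_zz"
"manus",6.37,0.79,10.26,1.25,9.83,1.17,2.64,1.11,4.02,1.01,1.68,0.74,"int_ext","abd_add"
"antebrachium",9.82,1.23,32.68,2.64,26.86,1.85,6.84,1.12,24.32,4.67,-5.33,5.57,"abd_add","int_ext"
"brachium",29.87,4.06,51.46,8.07,43.69,7.16,8.85,3.27,17.16,2.96,19.12,9.8,"abd_add","int_ext"
"pes",18.86,1.59,8.93,0.8,17.34,0.51,5.36,0.82,7.29,0.76,2.4,0.98,"abd_add","int_ext"
"crus",15.48,1.95,28.55,1.98,28,1.69,3.77,3.18,29.28,2.49,3.14,6.8,"abd_add","int_ext"
"thigh",100.61,9.24,79.74,12.24,109.91,11.69,19,3.27,28.01,3.71,38.78,3.51,"abd_add","int_ext"
"head",253.67,5.53,191.61,16.2,248.6,10.24,51.79,5.16,78.18,6.94,82.2,7.29,"int_ext","abd_add"
"neck",155.04,15.89,160.27,11.19,142.75,19.62,50,7.23,34.66,3.88,46.17,9.04,"int_ext","abd_add"
"abdomen",1164.68,185.52,737.53,105.81,1457.73,213.35,162.88,20.11,246.5,58.04,70.23,283.44,"int_ext","abd_add"
"thorax",2811.71,160.47,1350.62,35.68,2825.1,170.99,318.51,10.12,701.83,43.53,1004.15,153.99,"int_ext","abd_add"
"tail",8.21,1.41,60.7,4.37,48.5,4.27,21.19,2.41,-435.32,1915.34,-2039.36,628.28,"abd_add","int_ext"
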