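# plesiomass equation table, schema_version 1.0
"id","group","response","predictor","form","method","slope","intercept","ll_numerator","ll_scale","ll_exponent","ll_offset","n","r_squared","aicc","mean_abs_pe","sd_abs_pe","units_in","units_out","preferred"
"eq8","missing_element","max_rib_arc_length","trunk_length","log-linear","PGLS",1.0019,-0.4365,NA,NA,NA,NA,24,NA,-36.85,15.22,NA,"mm","mm",FALSE
"eq9","missing_element","max_rib_arc_length","trunk_length","log-linear","OLS",1.0123,-0.5068,NA,NA,NA,NA,24,0.903,-54.88,14.29,NA,"mm","mm",TRUE
"eq10","missing_element","tail_length","femur_length","log-linear","PGLS",0.9706,0.6887,NA,NA,NA,NA,22,NA,-26.76,19.8,NA,"mm","mm",FALSE
"eq11","missing_element","tail_length","femur_distal_width","log-linear","PGLS",0.778,1.4225,NA,NA,NA,NA,22,NA,-28.54,16.32,NA,"mm","mm",FALSE
"eq12","missing_element","tail_length","trunk_length","log-linear","PGLS",0.8434,0.4895,NA,NA,NA,NA,22,NA,-41.25,12.77,NA,"mm","mm",FALSE
"eq13","missing_element","tail_length","femur_length","log-linear","OLS",0.8074,1.0675,NA,NA,NA,NA,22,0.6098,-34.94,19.56,NA,"mm","mm",FALSE
"eq14","missing_element","tail_length","femur_distal_width","log-linear","OLS",0.8231,1.2899,NA,NA,NA,NA,22,0.7217,-42.38,17.42,NA,"mm","mm",FALSE
"eq15","missing_element","tail_length","trunk_length","log-linear","OLS",0.8414,0.4803,NA,NA,NA,NA,22,0.8175,-51.66,13.43,NA,"mm","mm",TRUE
"eq16","missing_element","skull_neck_ratio","cervical_count","log-linear","PGLS",-1.4695,1.556,NA,NA,NA,NA,37,NA,-74.11,19,NA,"","",FALSE
"eq17","missing_element","skull_neck_ratio","cervical_count","log-linear","OLS",-1.4851,1.5568,NA,NA,NA,NA,37,NA,-69.1,18.63,NA,"","",FALSE
"eq18","missing_element","skull_neck_ratio","cervical_count","log-logistic","LL4",NA,NA,1.2808,1.5844,10.2843,-1.4398,37,NA,-94.18,11.92,NA,"","",FALSE
"eq19","missing_element","skull_neck_ratio","cervical_count","log-linear","OLS",-1.5065,1.5916,NA,NA,NA,NA,40,NA,-73.7,19.07,NA,"","",FALSE
"eq20","missing_element","skull_neck_ratio","cervical_count","log-logistic","LL4",NA,NA,1.3067,1.5937,10.2847,-1.4684,40,NA,-103.58,11.86,NA,"","",TRUE
"table2_skl_cn","mass_ols","body_mass","skl_cn","log-linear","OLS",2.8228,-0.38,NA,NA,NA,NA,19,0.9169,NA,50.76,43.57,"m","kg",TRUE
"table2_trunk","mass_ols","body_mass","trunk","log-linear","OLS",2.9292,2.4367,NA,NA,NA,NA,27,0.9836,NA,17.73,13.94,"m","kg",TRUE
"table2_vertebral_volume","mass_ols","body_mass","vertebral_volume","log-linear","OLS",1.0257,6.5333,NA,NA,NA,NA,14,0.9768,NA,22.65,12.4,"m","kg",TRUE
"table2_vertebral_area","mass_ols","body_mass","vertebral_area","log-linear","OLS",1.4711,6.289,NA,NA,NA,NA,14,0.9657,NA,25.83,25.16,"m","kg",TRUE
"table2_humerus_length","mass_ols","body_mass","humerus_length","log-linear","OLS",2.9617,4.251,NA,NA,NA,NA,26,0.8314,NA,60.67,79.48,"m","kg",TRUE
"table2_humerus_width","mass_ols","body_mass","humerus_width","log-linear","OLS",3.4183,5.3925,NA,NA,NA,NA,26,0.823,NA,63.76,67.39,"m","kg",TRUE
"table2_femur_length","mass_ols","body_mass","femur_length","log-linear","OLS",2.5684,4.0469,NA,NA,NA,NA,24,0.815,NA,73.21,107.42,"m","kg",TRUE
"table2_femur_width","mass_ols","body_mass","femur_width","log-linear","OLS",3.1556,5.2276,NA,NA,NA,NA,24,0.9055,NA,43.24,47.89,"m","kg",TRUE
"table2_coracoid_length","mass_ols","body_mass","coracoid_length","log-linear","OLS",2.5219,3.7767,NA,NA,NA,NA,17,0.9041,NA,47.03,33.08,"m","kg",TRUE
"table2_coracoid_width","mass_ols","body_mass","coracoid_width","log-linear","OLS",2.7437,4.612,NA,NA,NA,NA,24,0.9144,NA,40.64,31.44,"m","kg",TRUE
"table2_pubic_length","mass_ols","body_mass","pubic_length","log-linear","OLS",2.3601,4.1001,NA,NA,NA,NA,19,0.8559,NA,53.51,53.45,"m","kg",TRUE
"table2_pubic_width","mass_ols","body_mass","pubic_width","log-linear","OLS",2.9436,4.4309,NA,NA,NA,NA,20,0.9076,NA,44.75,35.66,"m","kg",TRUE
"table2_ischium_length","mass_ols","body_mass","ischium_length","log-linear","OLS",2.0943,3.9879,NA,NA,NA,NA,21,0.8305,NA,63.4,74.11,"m","kg",TRUE
"table2_ischium_width","mass_ols","body_mass","ischium_width","log-linear","OLS",2.9946,4.8402,NA,NA,NA,NA,23,0.9455,NA,35.44,41.75,"m","kg",TRUE
"table3_skl_cn","mass_pgls","body_mass","skl_cn","log-linear","PGLS",4.1469,-1.8817,NA,NA,NA,NA,18,NA,28.69,NA,NA,"m","kg",FALSE
"table3_trunk","mass_pgls","body_mass","trunk","log-linear","PGLS",2.816,2.4871,NA,NA,NA,NA,26,NA,-34.7,NA,NA,"m","kg",FALSE
"table3_vertebral_volume","mass_pgls","body_mass","vertebral_volume","log-linear","PGLS",0.9924,6.3991,NA,NA,NA,NA,13,NA,1.94,NA,NA,"m","kg",FALSE
"table3_vertebral_area","mass_pgls","body_mass","vertebral_area","log-linear","PGLS",1.4067,6.1423,NA,NA,NA,NA,13,NA,5.74,NA,NA,"m","kg",FALSE
"table3_humerus_length","mass_pgls","body_mass","humerus_length","log-linear","PGLS",3.1155,4.154,NA,NA,NA,NA,25,NA,30.76,NA,NA,"m","kg",FALSE
"table3_humerus_width","mass_pgls","body_mass","humerus_width","log-linear","PGLS",3.0397,5.1027,NA,NA,NA,NA,25,NA,21.55,NA,NA,"m","kg",FALSE
"table3_femur_length","mass_pgls","body_mass","femur_length","log-linear","PGLS",3.3919,4.2695,NA,NA,NA,NA,23,NA,31.41,NA,NA,"m","kg",FALSE
"table3_femur_width","mass_pgls","body_mass","femur_width","log-linear","PGLS",2.6469,4.8335,NA,NA,NA,NA,23,NA,13.68,NA,NA,"m","kg",FALSE
"table3_coracoid_length","mass_pgls","body_mass","coracoid_length","log-linear","PGLS",2.1043,3.6265,NA,NA,NA,NA,16,NA,8.1,NA,NA,"m","kg",FALSE
"table3_coracoid_width","mass_pgls","body_mass","coracoid_width","log-linear","PGLS",2.8824,4.6642,NA,NA,NA,NA,23,NA,-6.18,NA,NA,"m","kg",FALSE
"table3_pubic_length","mass_pgls","body_mass","pubic_length","log-linear","PGLS",2.2077,4.0294,NA,NA,NA,NA,18,NA,17.35,NA,NA,"m","kg",FALSE
"table3_pubic_width","mass_pgls","body_mass","pubic_width","log-linear","PGLS",3.0576,4.4702,NA,NA,NA,NA,19,NA,5.33,NA,NA,"m","kg",FALSE
"table3_ischium_length","mass_pgls","body_mass","ischium_length","log-linear","PGLS",1.97,3.8969,NA,NA,NA,NA,20,NA,19.48,NA,NA,"m","kg",FALSE
"table3_ischium_width","mass_pgls","body_mass","ischium_width","log-linear","PGLS",3.064,4.8734,NA,NA,NA,NA,22,NA,-0.19,NA,NA,"m","kg",FALSE
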