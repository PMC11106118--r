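polymer,dominant_size_um,count_per_ml_mean,count_per_ml_sd,rsd_printed_pct,mass_ug_per_ml_mean,mass_ug_per_ml_sd,recovery_printed_pct,density_g_cm3,suspension_solution
PA6,10-50,1287,387,30,69,53,111,1.14,0.9 mol/L KI in detergent
PE,10-450,3210,957,30,63463,25783,105,0.94,ethanol:detergent (55:45 v/v)
PET,10-100,2613,325,12,359,57,82,1.38,4.0 mol/L KI in detergent
PP,10-500,358,71,20,215,83,62,0.91,ethanol:detergent (50:50 v/v)
PS,10-60,941,321,34,322,137,75,1.05,0.5 mol/L KI in detergent
PVC,20-350,836,138,17,7562,2850,92,1.40,5.0 mol/L KI in detergent
PA12,25-50,478,295,62,NA,NA,NA,1.01,detergent
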