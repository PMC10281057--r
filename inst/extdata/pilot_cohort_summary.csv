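variable,label,mean_all,sd_all,range_min,range_max,mean_women,sd_women,n_women,mean_men,sd_men,n_men,p_printed,sd_decimals
id_adl,ID-ADL,3.50,1.03,2,6,3.50,1.09,12,3.50,1.00,4,1.0000,2
age,Age (years),86.00,7.81,72,100,87.00,8.02,12,83.00,7.26,4,0.3932,2
length_of_stay,Length of stay (days),897.50,673.99,78,1730,1092.50,668.77,12,312.50,151.58,4,0.0400,2
height_cm,Body height (cm),150.39,9.08,137,174,146.94,5.71,12,160.75,10.11,4,0.0037,2
weight_kg,Body weight (kg),45.94,9.55,27.8,64.1,43.11,8.26,12,54.45,8.78,4,0.0343,2
bmi,BMI (kg/m2),20.16,3.00,13.90,25.70,19.90,3.38,12,20.95,1.48,4,0.5633,2
smi,SMI (kg/m2),5.10,1.06,3.15,7.18,4.80,0.97,12,5.99,0.88,4,0.0473,2
arm_muscle_kg,Muscle mass of the dominant upper limb (kg),1.42,0.48,0.72,2.60,1.22,0.28,12,2.04,0.43,4,0.0000,2
mmse,MMSE score,14.56,6.89,1,23,13.92,7.46,12,21.25,7.68,4,0.1129,2
avg_velocity_ms,Average arm velocity (m/s),0.60,0.49,0.003,1.725,0.67,0.5,12,0.37,0.43,4,0.3071,1
avg_elevation_deg,Average arm elevation angle (deg),14.73,10.32,-4.29,32.46,14.50,11.2,12,15.42,8.45,4,0.8838,1
grip_kg,Dominant handgrip strength (kg),11.44,6.40,0.00,24.50,8.82,3.72,12,19.30,6.66,4,0.0013,2
active_flexion_deg,Dominant active shoulder flexion (deg),116.56,27.85,70,160,112.92,28.56,12,127.50,25.98,4,0.3827,2
passive_flexion_deg,Dominant passive shoulder flexion (deg),137.50,18.71,105,170,138.33,18.75,12,135.00,21.21,4,0.7693,2
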