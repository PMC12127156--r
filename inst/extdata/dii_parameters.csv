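component,global_mean,global_sd,effect_score,unit
alcohol,13.98,3.72,-0.278,g/d
vitamin_b12,5.15,2.70,0.106,ug/d
vitamin_b6,1.47,0.74,-0.365,mg/d
beta_carotene,3718,1720,-0.584,ug/d
caffeine,8.05,6.67,-0.110,g/d
carbohydrate,272.2,40,0.097,g/d
cholesterol,279.4,51.2,0.110,mg/d
energy,2056,338,0.180,kcal/d
total_fat,71.4,19.4,0.298,g/d
fiber,18.8,4.9,-0.663,g/d
folic_acid,273,70.7,-0.190,ug/d
iron,13.35,3.71,0.032,mg/d
magnesium,310.1,139.4,-0.484,mg/d
mufa,27,6.1,-0.009,g/d
niacin,25.9,11.77,-0.246,mg/d
protein,79.4,13.9,0.021,g/d
pufa,13.88,3.76,-0.337,g/d
riboflavin,1.70,0.79,-0.068,mg/d
saturated_fat,28.6,8,0.373,g/d
selenium,67,25.1,-0.191,ug/d
thiamin,1.70,0.66,-0.098,mg/d
vitamin_a,983.9,518.6,-0.401,RE/d
vitamin_c,118.2,43.46,-0.424,mg/d
vitamin_d,6.26,2.21,-0.446,ug/d
vitamin_e,8.73,1.49,-0.419,mg/d
zinc,9.84,2.19,-0.313,mg/d
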