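# Reference effect sizes (counts, with 95% CIs and printed integer percent differences) that the default model configuration emulates.
scenario,started_mean,started_ci_lo,started_ci_hi,started_pct,started_significant,completed_mean,completed_ci_lo,completed_ci_hi,completed_pct,completed_significant,nas_cases_mean,nas_cases_ci_lo,nas_cases_ci_hi,nas_cases_pct,nas_cases_significant
Baseline,570.7,563.35,578.05,NA,NA,418.34,411.83,424.85,NA,NA,3697.32,3685.95,3708.69,NA,NA
MOT,1819.17,1811.82,1826.52,219,TRUE,1329.48,1322.97,1335.99,218,TRUE,3255.66,3244.29,3267.03,-12,TRUE
Patient Navigators,1110.22,1102.87,1117.57,95,TRUE,807.92,801.41,814.43,93,TRUE,3505.66,3494.29,3517.03,-5,TRUE
Capacity Increase,679.2,671.85,686.55,19,TRUE,497.38,490.87,503.89,19,TRUE,3660.91,3649.54,3672.28,-1,TRUE
Peer Recovery Coaches,567.83,560.48,575.18,-1,FALSE,473.89,467.38,480.40,13,TRUE,3576.29,3564.92,3587.66,-3,TRUE
Navigators + Coaches,1110.8,1103.45,1118.15,95,TRUE,928.38,921.87,934.89,122,TRUE,3234.96,3223.59,3246.33,-13,TRUE
MOT + Navigators,2352.22,2344.87,2359.57,312,TRUE,1715.83,1709.32,1722.34,310,TRUE,3061.97,3050.60,3073.34,-17,TRUE
MOT + Capacity,1924.75,1917.40,1932.10,237,TRUE,1408.04,1401.53,1414.55,237,TRUE,3207.71,3196.34,3219.08,-13,TRUE
MOT + Coaches,1810.38,1803.03,1817.73,217,TRUE,1513.61,1507.10,1520.12,262,TRUE,2818.27,2806.90,2829.64,-24,TRUE
MOT + Navigators + Coaches,2359.01,2351.66,2366.36,313,TRUE,1968.82,1962.31,1975.33,371,TRUE,2506.03,2494.66,2517.40,-32,TRUE
Navigators + Capacity,1174.2,1166.85,1181.55,106,TRUE,857.9,851.45,864.47,105,TRUE,3485.22,3473.85,3496.59,-6,TRUE
Coaches + Capacity,692.3,684.95,699.65,21,TRUE,577.8,571.30,584.32,38,TRUE,3481.96,3470.59,3493.33,-6,TRUE
Capacity + Navigators + Coaches,1174.44,1167.09,1181.79,106,TRUE,982.05,975.54,988.56,135,TRUE,3197.85,3186.48,3209.22,-14,TRUE
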