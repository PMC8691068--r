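# Reference Medicaid incremental-cost results (dollars) that the default model configuration emulates.
# percent_diff is the printed integer percent difference from baseline; significant=FALSE marks "(NS)" cells.
scenario,mother_opioid_treatment,nas_treatment,total,ci_lo,ci_hi,percent_diff,significant
Baseline,5004,266644,271648,270756,272540,NA,NA
MOT,15972,234447,250419,249527,251311,-8,TRUE
Patient Navigators,9768,252321,262089,261197,262981,-4,TRUE
Capacity Increase,5963,264207,270170,269277,271062,-1,FALSE
Peer Recovery Coaches,5232,256963,262195,261302,263086,-3,TRUE
Navigators + Coaches,10229,233914,244143,243250,245035,-10,TRUE
MOT + Navigators,20783,221061,241844,240951,242736,-11,TRUE
MOT + Capacity,16960,230935,247895,247002,248786,-9,TRUE
MOT + Coaches,16789,204083,220872,219980,221764,-19,TRUE
MOT + Navigators + Coaches,21789,179423,201212,200320,202104,-26,TRUE
Navigators + Capacity,10338,251347,261685,260793,262577,-4,TRUE
Coaches + Capacity,6419,251748,258167,257275,259059,-5,TRUE
Capacity + Navigators + Coaches,10845,230448,241293,240401,242185,-11,TRUE
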