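# Reference total-system incremental-cost results (dollars) that the default model configuration emulates.
scenario,medicaid,overdose_death,living_with_oud,special_education,total,ci_lo,ci_hi,percent_diff,significant
Baseline,271648,254888,82583,22867,631986,625924,638048,NA,NA
MOT,250419,262233,60872,20086,593610,587548,599672,-6,TRUE
Patient Navigators,262090,257922,73095,21632,614739,608677,620800,-3,TRUE
Capacity Increase,270169,253869,80790,22654,627482,621420,633543,-1,FALSE
Peer Recovery Coaches,262194,251909,81255,22024,617382,611321,623444,-2,TRUE
Navigators + Coaches,244143,241284,70635,20064,576126,570065,582188,-9,TRUE
MOT + Navigators,241843,260537,51588,18909,572877,566816,578939,-9,TRUE
MOT + Capacity,247894,252608,58892,19792,579186,573125,585248,-8,TRUE
MOT + Coaches,220872,230673,56888,17488,525921,519859,531982,-17,TRUE
MOT + Navigators + Coaches,201212,218299,45713,15360,480584,474523,486646,-24,TRUE
Navigators + Capacity,261685,252737,72111,21529,608062,602001,614124,-4,TRUE
Coaches + Capacity,258167,245379,78789,21581,603916,597854,609978,-4,TRUE
Capacity + Navigators + Coaches,241293,240841,69317,19793,571243,565182,577306,-10,TRUE
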