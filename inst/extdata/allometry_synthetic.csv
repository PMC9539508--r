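key,level,measure_height,a,b
tree,lifeform,130,-2.0,2.40
tree,lifeform,50,-2.4,2.30
tree,lifeform,10,-2.9,2.25
shrub,lifeform,130,-2.2,2.35
shrub,lifeform,50,-2.6,2.25
shrub,lifeform,10,-3.0,2.20
ACA001,species,130,-2.15,2.38
ACA001,species,50,-2.55,2.28
ACA001,species,10,-2.95,2.22
EUC001,species,130,-1.95,2.42
EUC001,species,50,-2.35,2.32
EUC001,species,10,-2.85,2.26
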