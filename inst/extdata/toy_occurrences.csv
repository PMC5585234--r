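taxon,genus,rank,lat,lon,depth_m,epoch,zooxanthellate
Acropora_a,Acropora,species,10.2,100.2,5,modern,TRUE
Acropora_a,Acropora,species,10.7,100.9,59.9,modern,TRUE
Porites_b,Porites,species,10.5,100.5,60.0,modern,TRUE
Porites_b,Porites,species,11.5,100.5,60.1,modern,TRUE
Tubastraea_c,Tubastraea,species,11.2,100.2,10,modern,FALSE
Tubastraea_c,Tubastraea,species,11.8,100.8,80,modern,FALSE
Favia_d,Favia,species,11.4,100.4,20,modern,TRUE
Favia_d,Favia,species,11.9,100.1,30,modern,TRUE
Porites_e,Porites,species,12.5,100.5,70,modern,TRUE
Acropora_f,Acropora,species,12.2,100.7,15,modern,TRUE
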