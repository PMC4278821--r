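taxon,level,guild,gap,ground,canopy
Eptesicus sp.,SPECIES_GROUP,LRE,241,22,26
Hypsugo savii,SPECIES,MRE,7,0,3
Myotis brandtii,SPECIES,SRE,33,33,29
Myotis bechsteinii,SPECIES,SRE,1,2,3
Myotis daubentonii,SPECIES,SRE,211,570,280
Myotis emarginatus,SPECIES,SRE,47,228,137
Myotis myotis,SPECIES,SRE,221,578,24
Myotis mystacinus,SPECIES,SRE,19,132,19
Myotis nattereri,SPECIES,SRE,4,13,0
Nyctalus sp.,SPECIES_GROUP,LRE,223,13,13
Pipistrellus kuhlii,SPECIES,MRE,1420,436,413
Pipistrellus nathusii,SPECIES,MRE,8954,1271,773
Pipistrellus pipistrellus,SPECIES,MRE,41111,38402,33827
Pipistrellus pygmaeus,SPECIES,MRE,38,130,75
Plecotus sp.,SPECIES_GROUP,SRE,13,20,8
Vespertilio murinus,SPECIES,LRE,4,0,0
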