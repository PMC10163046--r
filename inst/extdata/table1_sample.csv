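species_id,scientific_name,vernacular_en,lineage,subgroup,class,order,family,iucn_status,n_occurrences,alien,potential_crop,solid_wood,burned_wood,wild_food,wild_use,mellifera,forage_pasture,decontamination,riverbank_erosion,hedge_crop_yield,reduce_species_damage,reduce_runoff,keystone_species,reduce_landslide,scientific_interest,iconic_species,endangered_habitat
salix_alba,Salix alba,White willow,tracheophyte,angiosperm,Magnoliopsida,Malpighiales,Salicaceae,LC,2500,FALSE,1,1,1,0,1,1,1,1,1,0,,0,1,1,1,1,0
salix_caprea,Salix caprea,Goat willow,tracheophyte,angiosperm,Magnoliopsida,Malpighiales,Salicaceae,LC,4100,FALSE,1,1,0,0,1,1,1,1,0,1,,1,1,1,1,1,0
populus_tremula,Populus tremula,Aspen,tracheophyte,angiosperm,Magnoliopsida,Malpighiales,Salicaceae,LC,3200,FALSE,1,1,1,0,1,1,0,1,1,1,,1,0,0,1,1,0
alnus_glutinosa,Alnus glutinosa,Common alder,tracheophyte,angiosperm,Magnoliopsida,Fagales,Betulaceae,LC,2900,FALSE,1,1,1,0,1,1,0,0,1,1,,0,0,1,1,1,0
betula_pendula,Betula pendula,White birch,tracheophyte,angiosperm,Magnoliopsida,Fagales,Betulaceae,LC,5200,FALSE,1,1,1,0,1,0,1,1,0,1,,1,0,0,1,1,0
vulpes_vulpes,Vulpes vulpes,Red fox,vertebrate,mammal,Mammalia,Carnivora,Canidae,LC,8100,FALSE,,,,0,1,,,,0,,1,,1,0,1,1,0
lynx_lynx,Lynx lynx,Eurasian lynx,vertebrate,mammal,Mammalia,Carnivora,Felidae,EN,410,FALSE,,,,0,0,,,,0,,0,,1,1,1,1,1
lagopus_muta,Lagopus muta,Rock ptarmigan,vertebrate,bird,Aves,Galliformes,Phasianidae,NT,950,FALSE,,,,1,1,,,,0,,0,,0,,0,1,1
lyrurus_tetrix,Lyrurus tetrix,Black grouse,vertebrate,bird,Aves,Galliformes,Phasianidae,LC,1300,FALSE,,,,1,1,,,,0,,0,,0,,0,1,1
canis_lupus,Canis lupus,Grey wolf,vertebrate,mammal,Mammalia,Carnivora,Canidae,EN,160,FALSE,,,,0,0,,,,0,,-1,,1,1,1,1,0
anas_platyrhynchos,Anas platyrhynchos,Mallard,vertebrate,bird,Aves,Anseriformes,Anatidae,LC,6200,FALSE,,,,1,0,,,,0,,0,,1,,1,0,0
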