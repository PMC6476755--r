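botanical_name,growth_form,life_history,native_status,regional_distribution,floral_display_mm,trichome_density,leaf_area_mm2,root_system,leaf_phenology,soil_most_soils,soil_heavy_clay,soil_sandy_loam,established_strategy,max_height_mm,associated_floristic_diversity,flowering_months,pollinator_support,commercially_available
Agrostis capillaris,grass,perennial,native,true,?,?,35,adventitious,?,?,?,?,CSR,600,12.0,6;7;8,false,true
Festuca pratensis,grass,perennial,native,true,?,?,27,adventitious,?,?,?,?,CSR,1000,20.0,6;7,false,true
Phleum pratense,grass,perennial,native,true,?,?,35,adventitious,?,?,?,?,C,1600,16.0,6;7;8,false,true
Dactylis glomerata,grass,perennial,native,true,?,?,27,adventitious,?,?,?,?,C,1000,16.0,5;6;7;8,true,true
Alopecurus pratensis,grass,perennial,native,true,?,?,27,adventitious,?,?,?,?,C,1000,16.0,4;5;6,false,true
Festuca rubra agg.,grass,perennial,native,true,?,?,17,adventitious,?,?,?,?,CSR,1000,16.0,5;6;7,false,true
Festuca arundinacea,grass,perennial,native,true,?,?,17,adventitious,?,?,?,?,C,2100,20.0,6;7;8,false,true
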