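botanical_name,growth_form,life_history,native_status,regional_distribution,floral_display_mm,trichome_density,leaf_area_mm2,root_system,leaf_phenology,soil_most_soils,soil_heavy_clay,soil_sandy_loam,established_strategy,max_height_mm,associated_floristic_diversity,flowering_months,pollinator_support,commercially_available
Trifolium pratense,forb,perennial,native,true,12,numerous,30,tap-root,evergreen,true,?,?,?,?,?,5;6;7;8;9,true,true
Trifolium repens,forb,perennial,native,true,12,sparse,30,adventitious,evergreen,true,?,?,?,?,?,6;7;8;9,true,true
Centaurea nigra,forb,perennial,native,true,12,numerous,30,tap-root,estival,true,?,?,?,?,?,6;7;8;9,true,true
Taraxacum officinale agg.,forb,perennial,native,true,12,sparse,30,tap-root,evergreen,true,?,?,?,?,?,3;4;5;6;7;8;9;10,true,true
Stachys sylvatica,forb,perennial,native,true,12,numerous,30,tap-root,estival,true,?,?,?,?,?,6;7;8;9,true,true
Leucanthemum vulgare,forb,perennial,native,true,12,sparse,20,adventitious,evergreen,true,?,?,?,?,?,5;6;7;8;9,true,true
Prunella vulgaris,forb,perennial,native,true,8,numerous,30,?,evergreen,true,?,?,?,?,?,6;7;8;9,true,false
Lotus corniculatus,forb,perennial,native,true,12,sparse,30,tap-root,estival,true,?,?,?,?,?,6;7;8;9,true,true
Daucus carota,forb,perennial,native,true,8,sparse,30,tap-root,evergreen,true,?,?,?,?,?,6;7;8,true,true
Achillea millefolium,forb,perennial,native,true,8,sparse,30,tap-root,evergreen,true,?,?,?,?,?,6;7;8;9,true,true
Galium verum,forb,perennial,native,true,8,numerous,20,?,evergreen,true,?,?,?,?,?,6;7;8;9,true,false
Ranunculus acris,forb,perennial,native,true,12,sparse,20,tap-root,estival,true,?,?,?,?,?,4;5;6;7;8;9,true,true
Silene dioica,forb,perennial,native,true,12,sparse,20,tap-root,estival,true,?,?,?,?,?,3;4;5;6;7;8;9;10,true,true
Veronica chamaedrys,forb,perennial,native,true,12,numerous,30,adventitious,evergreen,false,?,?,?,?,?,3;4;5;6;7,true,true
Hypochaeris radicata,forb,perennial,native,true,12,numerous,20,adventitious,evergreen,false,?,?,?,?,?,6;7;8;9,true,true
Primula vulgaris,forb,perennial,native,true,12,numerous,30,?,evergreen,false,?,?,?,?,?,3;4;5,true,true
Heracleum sphondylium,forb,perennial,native,true,12,numerous,20,tap-root,estival,false,?,?,?,?,?,6;7;8;9,true,true
Vicia cracca,forb,perennial,native,true,8,numerous,30,tap-root,estival,false,?,?,?,?,?,6;7;8,true,true
Potentilla erecta,forb,perennial,native,true,12,?,20,adventitious,estival,false,?,?,?,?,?,5;6;7;8;9,true,true
Scrophularia nodosa,forb,perennial,native,true,?,sparse,30,tap-root,estival,false,?,?,?,?,?,6;7;8;9,true,true
Knautia arvensis,forb,perennial,native,true,12,sparse,20,tap-root,estival,false,?,?,?,?,?,7;8;9,true,true
Malva moschata,forb,perennial,native,true,?,sparse,20,tap-root,evergreen,false,?,?,?,?,?,7;8,true,true
Potentilla anserina,forb,perennial,native,true,12,sparse,20,tap-root,estival,false,?,?,?,?,?,6;7;8,true,true
Geranium pratense,forb,perennial,native,true,12,sparse,20,tap-root,estival,false,?,?,?,?,?,6;7;8;9,true,true
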