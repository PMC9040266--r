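# Synthetic reconstruction of an MGnify-style biome lineage list with
# per-biome sample counts. Built to match published summary structure
# (6 layers; 133 nodes; 114 biomes; per-layer node counts 1/4/7/22/56/43;
# 22 samples for the Throat biome; 125,823 samples in total). The lineages
# and counts are NOT the original supplementary table.
# lineage<TAB>n_samples
Root	1481
Root-Engineered	362
Root-Environmental	14
Root-Host_associated	48
Root-Mixed	390
Root-Engineered-Food_production	618
Root-Engineered-Wastewater	4
Root-Environmental-Aquatic	825
Root-Environmental-Terrestrial	163
Root-Host_associated-Human	630
Root-Host_associated-Mammals	368
Root-Host_associated-Plants	63
Root-Engineered-Food_production-Dairy_products	114
Root-Engineered-Food_production-Fermented_vegetables	170
Root-Engineered-Wastewater-Activated_Sludge	494
Root-Engineered-Wastewater-Industrial_wastewater	182
Root-Engineered-Wastewater-Water_and_sludge	32
Root-Environmental-Aquatic-Freshwater	313
Root-Environmental-Aquatic-Marine	127
Root-Environmental-Aquatic-Non_marine_Saline_and_Alkaline	328
Root-Environmental-Aquatic-Sediment	510
Root-Environmental-Aquatic-Thermal_springs	115
Root-Environmental-Terrestrial-Deep_subsurface	770
Root-Environmental-Terrestrial-Soil	114
Root-Host_associated-Human-Circulatory_system	87
Root-Host_associated-Human-Digestive_system	993
Root-Host_associated-Human-Reproductive_system	67
Root-Host_associated-Human-Respiratory_system	68
Root-Host_associated-Human-Skin	7
Root-Host_associated-Mammals-Digestive_system	240
Root-Host_associated-Mammals-Respiratory_system	1405
Root-Host_associated-Mammals-Skin	50
Root-Host_associated-Plants-Rhizoplane	1425
Root-Host_associated-Plants-Rhizosphere	63
Root-Engineered-Food_production-Dairy_products-Cheese	262
Root-Engineered-Food_production-Dairy_products-Yogurt	25
Root-Engineered-Food_production-Fermented_vegetables-Kimchi	469
Root-Engineered-Food_production-Fermented_vegetables-Sauerkraut	136
Root-Engineered-Wastewater-Industrial_wastewater-Agricultural_wastewater	383
Root-Engineered-Wastewater-Industrial_wastewater-Contaminated	43
Root-Engineered-Wastewater-Industrial_wastewater-Petrochemical	98
Root-Engineered-Wastewater-Water_and_sludge-Sludge	157
Root-Engineered-Wastewater-Water_and_sludge-Wetlands	207
Root-Environmental-Aquatic-Freshwater-Groundwater	305
Root-Environmental-Aquatic-Freshwater-Ice	631
Root-Environmental-Aquatic-Freshwater-Lake	59
Root-Environmental-Aquatic-Freshwater-Lentic	176
Root-Environmental-Aquatic-Freshwater-Pond	505
Root-Environmental-Aquatic-Freshwater-River	14
Root-Environmental-Aquatic-Marine-Abyssal_zone	175
Root-Environmental-Aquatic-Marine-Coastal	9596
Root-Environmental-Aquatic-Marine-Hydrothermal_vents	1157
Root-Environmental-Aquatic-Marine-Intertidal_zone	42
Root-Environmental-Aquatic-Marine-Neritic_zone	46
Root-Environmental-Aquatic-Marine-Oceanic	50
Root-Environmental-Aquatic-Marine-Pelagic	518
Root-Environmental-Aquatic-Non_marine_Saline_and_Alkaline-Alkaline	181
Root-Environmental-Aquatic-Non_marine_Saline_and_Alkaline-Hypersaline	564
Root-Environmental-Aquatic-Non_marine_Saline_and_Alkaline-Saline	318
Root-Environmental-Aquatic-Non_marine_Saline_and_Alkaline-Soda_lake	77
Root-Environmental-Aquatic-Thermal_springs-Geysers	447
Root-Environmental-Aquatic-Thermal_springs-Hot_springs	246
Root-Environmental-Terrestrial-Soil-Agricultural_land	183
Root-Environmental-Terrestrial-Soil-Clay	512
Root-Environmental-Terrestrial-Soil-Contaminated	296
Root-Environmental-Terrestrial-Soil-Desert_soil	42
Root-Environmental-Terrestrial-Soil-Forest_soil	366
Root-Environmental-Terrestrial-Soil-Grasslands	57
Root-Environmental-Terrestrial-Soil-Loam	18
Root-Environmental-Terrestrial-Soil-Permafrost	752
Root-Environmental-Terrestrial-Soil-Sand	55
Root-Environmental-Terrestrial-Soil-Tundra_soil	759
Root-Host_associated-Human-Circulatory_system-Blood	26
Root-Host_associated-Human-Digestive_system-Esophagus	2331
Root-Host_associated-Human-Digestive_system-Large_intestine	1918
Root-Host_associated-Human-Digestive_system-Oral	672
Root-Host_associated-Human-Digestive_system-Small_intestine	220
Root-Host_associated-Human-Digestive_system-Stomach	702
Root-Host_associated-Human-Reproductive_system-Vagina	1037
Root-Host_associated-Human-Respiratory_system-Pulmonary_system	417
Root-Host_associated-Human-Skin-Foot	346
Root-Host_associated-Human-Skin-Hand	70
Root-Host_associated-Human-Skin-Nose	1195
Root-Host_associated-Mammals-Digestive_system-Large_intestine	158
Root-Host_associated-Mammals-Digestive_system-Oral	1244
Root-Host_associated-Mammals-Digestive_system-Small_intestine	2475
Root-Host_associated-Mammals-Digestive_system-Stomach	928
Root-Host_associated-Mammals-Respiratory_system-Pulmonary_system	80
Root-Host_associated-Plants-Rhizosphere-Rhizoplane	543
Root-Host_associated-Plants-Rhizosphere-Soil	62
Root-Environmental-Aquatic-Freshwater-Groundwater-Contaminated	10
Root-Environmental-Aquatic-Freshwater-Groundwater-Mine_drainage	69
Root-Environmental-Aquatic-Freshwater-Lake-Limnetic_zone	147
Root-Environmental-Aquatic-Freshwater-Lake-Littoral_zone	3169
Root-Environmental-Aquatic-Freshwater-River-Sediment	687
Root-Environmental-Aquatic-Marine-Coastal-Coral_reef	518
Root-Environmental-Aquatic-Marine-Coastal-Estuary	64
Root-Environmental-Aquatic-Marine-Hydrothermal_vents-Black_smokers	72
Root-Environmental-Aquatic-Marine-Hydrothermal_vents-Diffuse_flow	79
Root-Environmental-Aquatic-Marine-Intertidal_zone-Mangrove_swamp	3200
Root-Environmental-Aquatic-Marine-Intertidal_zone-Mudflats	92
Root-Environmental-Aquatic-Marine-Intertidal_zone-Salt_marsh	176
Root-Environmental-Aquatic-Marine-Oceanic-Aphotic_zone	12
Root-Environmental-Aquatic-Marine-Oceanic-Photic_zone	89
Root-Environmental-Terrestrial-Soil-Agricultural_land-Cropland	33
Root-Environmental-Terrestrial-Soil-Agricultural_land-Orchard	1312
Root-Environmental-Terrestrial-Soil-Contaminated-Heavy_metals	219
Root-Environmental-Terrestrial-Soil-Contaminated-Hydrocarbon	79
Root-Environmental-Terrestrial-Soil-Forest_soil-Boreal_forest	182
Root-Environmental-Terrestrial-Soil-Forest_soil-Tropical_rainforest	302
Root-Environmental-Terrestrial-Soil-Grasslands-Savanna	7
Root-Environmental-Terrestrial-Soil-Grasslands-Steppe	453
Root-Host_associated-Human-Circulatory_system-Blood-Plasma	288
Root-Host_associated-Human-Digestive_system-Large_intestine-Fecal	54752
Root-Host_associated-Human-Digestive_system-Large_intestine-Sigmoid_colon	203
Root-Host_associated-Human-Digestive_system-Oral-Gingiva	297
Root-Host_associated-Human-Digestive_system-Oral-Saliva	30
Root-Host_associated-Human-Digestive_system-Oral-Throat	22
Root-Host_associated-Human-Digestive_system-Oral-Tongue	403
Root-Host_associated-Human-Digestive_system-Small_intestine-Ileum	90
Root-Host_associated-Human-Digestive_system-Stomach-Gastric_mucosa	132
Root-Host_associated-Human-Reproductive_system-Vagina-Vaginal_fluid	3973
Root-Host_associated-Human-Respiratory_system-Pulmonary_system-Lung	1395
Root-Host_associated-Human-Respiratory_system-Pulmonary_system-Sputum	1079
Root-Host_associated-Human-Skin-Hand-Fingernail	72
Root-Host_associated-Human-Skin-Hand-Palm	482
Root-Host_associated-Mammals-Digestive_system-Large_intestine-Cecum	1152
Root-Host_associated-Mammals-Digestive_system-Large_intestine-Fecal	1247
Root-Host_associated-Mammals-Digestive_system-Oral-Saliva	514
Root-Host_associated-Mammals-Digestive_system-Oral-Throat	835
Root-Host_associated-Mammals-Digestive_system-Oral-Tongue	158
Root-Host_associated-Mammals-Digestive_system-Stomach-Gastric_mucosa	224
Root-Host_associated-Mammals-Respiratory_system-Pulmonary_system-Lung	513
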