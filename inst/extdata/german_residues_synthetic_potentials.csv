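id,name,sector,technical_potential_Mg_DM_a,usable_share,cellulose_min,cellulose_mean,cellulose_max,hemicellulose_min,hemicellulose_mean,hemicellulose_max,lignin_min,lignin_mean,lignin_max,nfc_min,nfc_mean,nfc_max,protein_min,protein_mean,protein_max,fats_oils_min,fats_oils_mean,fats_oils_max,ash_min,ash_mean,ash_max,n_sources,analysis_quality,newest_source_year
bark,Bark,forestry,1500000,1,0.20,0.26,0.32,0.10,0.15,0.20,0.29,0.34,0.40,,,,,,,,,,0.02,0.04,0.06,4,detailed,2021
wood_processing,By-products of wood processing industry,industry,3000000,1,0.35,0.42,0.48,0.18,0.24,0.30,0.24,0.28,0.33,,,,,,,,,,0.00,0.01,0.02,4,detailed,2020
industrial_waste_wood,Other industrial waste wood,industry,1500000,1,0.35,0.42,0.48,0.18,0.24,0.30,0.24,0.28,0.33,,,,,,,,,,0.00,0.01,0.03,5,detailed,2020
brewery_residues,Residues from breweries (brewer's spent grain),industry,500000,1,0.12,0.17,0.25,0.20,0.28,0.40,0.20,0.28,0.30,,,,0.15,0.24,0.31,,,,0.03,0.04,0.05,1,method_stated,2016
logging_residues_deciduous,Logging residues (deciduous),forestry,5700000,1,0.38,0.43,0.48,0.20,0.28,0.35,0.20,0.25,0.30,,,,,,,,,,0.00,0.01,0.02,6,detailed_with_series,2022
landscape_wood,Woody biomass from landscape management,other,2000000,1,0.38,0.44,0.50,0.20,0.27,0.34,0.20,0.24,0.28,,,,,,,,,,0.00,0.02,0.04,10,detailed,2021
waste_wood,Waste wood,municipal_waste_sewage,7500000,1,0.40,0.45,0.50,0.20,0.26,0.32,0.20,0.24,0.28,,,,,,,,,,0.01,0.02,0.05,10,detailed,2021
logging_residues_coniferous,Logging residues (coniferous),forestry,9500000,1,0.40,0.45,0.50,0.20,0.26,0.32,0.20,0.23,0.28,,,,,,,,,,0.00,0.01,0.02,4,detailed_with_series,2022
green_waste,Green waste,municipal_waste_sewage,5750000,1,0.25,0.32,0.40,0.12,0.17,0.22,0.15,0.20,0.25,,,,,,,,,,0.05,0.10,0.15,2,method_stated,2018
leaves,Leaves,other,5750000,1,0.15,0.21,0.28,0.10,0.14,0.18,0.15,0.20,0.25,,,,,,,,,,0.04,0.08,0.12,2,method_stated,2017
bakery_residues,Residues from bread and bakeries production,industry,500000,1,,,,,,,,,,0.55,0.65,0.75,0.08,0.12,0.16,0.02,0.05,0.09,0.01,0.02,0.03,2,detailed,2019
starch_residues,Residues from starch production,industry,1000000,0.8,0.10,0.17,0.22,,,,,,,0.45,0.53,0.60,0.04,0.07,0.10,,,,0.03,0.05,0.07,2,detailed,2019
milk_processing_residues,Residues from milk processing,industry,800000,1,,,,,,,,,,0.45,0.52,0.60,0.10,0.13,0.16,0.01,0.02,0.04,0.06,0.08,0.10,2,detailed,2020
sugar_residues,Residues from sugar production,industry,700000,1,0.10,0.18,0.25,0.08,0.14,0.20,,,,0.30,0.40,0.50,0.06,0.10,0.14,,,,0.04,0.07,0.10,4,detailed,2019
kitchen_canteen_waste,Kitchen and canteen wastes,municipal_waste_sewage,2080000,1,0.05,0.10,0.16,0.03,0.06,0.10,0.02,0.05,0.10,0.28,0.38,0.48,0.12,0.17,0.22,0.08,0.14,0.20,0.04,0.06,0.09,4,detailed,2021
bioethanol_residues,Residues from bioethanol production,industry,2020000,1,0.10,0.16,0.22,0.06,0.12,0.18,,,,0.15,0.23,0.32,0.15,0.22,0.30,,,,0.05,0.08,0.11,3,detailed,2018
cattle_solid_manure,Cattle solid manure,agriculture,8500000,1,0.18,0.24,0.30,0.12,0.18,0.24,0.10,0.14,0.18,0.10,0.16,0.22,0.10,0.14,0.18,,,,0.08,0.12,0.18,5,detailed_with_series,2022
roadside_stalks,Stalks from roadside,other,1200000,1,0.25,0.32,0.40,0.18,0.24,0.30,0.08,0.12,0.16,0.10,0.16,0.22,0.04,0.08,0.12,,,,0.05,0.08,0.12,5,detailed,2020
glycerol_biodiesel,Glycerol from biodiesel production,industry,277000,1,,,,,,,,,,,,,,,,0.90,0.95,0.99,0.01,0.03,0.06,1,method_stated,2020
oil_waste,Oil waste,municipal_waste_sewage,156000,1,,,,,,,,,,,,,,,,0.85,0.91,0.96,0.00,0.01,0.02,1,method_stated,2019
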