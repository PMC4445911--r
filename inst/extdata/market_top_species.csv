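species_id,family,n_for_sale,price_usd,status
Streptopelia_tranquebarica,Columbidae,7420,1.63,native
Zosterops_japonicus,Zosteropidae,6381,35.50,native
Lonchura_punctulata,Estrildidae,2649,1.50,native
Melopsittacus_undulatus,Psittacidae,956,7.70,alien
Padda_oryzivora,Estrildidae,928,10.47,alien
Acridotheres_grandis,Sturnidae,722,10.00,alien
Acridotheres_fuscus,Sturnidae,492,6.83,alien
Pycnonotus_sinensis,Pycnonotidae,465,10.03,native
Lonchura_striata,Estrildidae,437,2.40,native
Erythrura_gouldiae,Estrildidae,405,13.03,alien
Guaruba_guarouba,Psittacidae,5,8000.00,alien
Cacatua_leadbeateri,Psittacidae,2,7500.00,alien
Amazona_oratrix,Psittacidae,1,6666.67,alien
Ara_macao,Psittacidae,1,4000.00,alien
Cacatua_moluccensis,Psittacidae,2,3333.33,alien
Ara_chloropterus,Psittacidae,2,2083.33,alien
Cacatua_ophthalmica,Psittacidae,1,2000.00,alien
Primolius_auricollis,Psittacidae,5,1916.67,alien
Ara_ararauna,Psittacidae,18,1818.17,alien
Pionites_leucogaster,Psittacidae,4,1777.77,alien
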