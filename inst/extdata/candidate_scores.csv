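id,species,accession,description,camp_top_hit,camp_evalue,length,ampir_precursor,ampir_mature,multipep_antimicrobial,multipep_antibacterial
Hmet,Haemonchus contortus,A0A7I4Y4R3,Metridin-ShK toxin,NA,NA,84,0.996,NA,0.746,0.215
Tchis,Toxocara canis,A0A0B2V2B5,Histone 2A,Histone H2A,4e-75,126,0.992,NA,0.325,0.958
Tdes,Teladorsagia circumcincta,A0A2G9TVU4,Destabilase (Lysozyme),Lysozyme 3,4e-39,139,0.923,NA,0.440,0.049
Tsap,Teladorsagia circumcincta,transcript/25448 (iso-seq),Saposin-b,Caenopore-5,2e-09,104,0.864,NA,0.943,0.279
Tscp,Teladorsagia circumcincta,A0A2G9TU46,SCP-like protein,NA,NA,166,0.732,NA,0.003,0.000
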