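disease,bioterror,severity,economic,collaborate,epidemic
Rabies,no,yes,no,both,yes
Anthrax,yes,yes,yes,both,no
Brucellosis,yes,no,yes,both,no
Bovine Tuberculosis,no,no,yes,both,no
Highly Pathogenic Avian Influenza,yes,yes,yes,at least one,yes
Echinococcosis,no,no,yes,at least one,no
Leptospirosis,no,no,yes,at least one,yes
Q Fever,yes,no,yes,at least one,no
Rift Valley Fever,yes,yes,yes,neither,yes
Plague,yes,yes,no,at least one,yes
Human African Trypanosomiasis,no,yes,yes,neither,no
Leishmaniasis,no,no,no,at least one,yes
Toxoplasmosis,no,no,no,both,no
Porcine Cysticercosis,no,no,yes,neither,no
Ebola Virus Disease,yes,yes,no,neither,yes
Lassa Fever,yes,yes,no,neither,yes
Nipah Virus Infection,no,yes,no,neither,yes
West Nile Fever,no,no,no,at least one,yes
Crimean-Congo Haemorrhagic Fever,no,yes,no,at least one,yes
Bacterial Food-Borne Zoonoses,no,no,yes,both,yes
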