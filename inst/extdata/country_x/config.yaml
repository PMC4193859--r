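# Country X worked example: five criteria agreed by ten representatives of
# the human and animal health agencies, one categorical question each, and
# the 20-entry zoonosis list compiled before the group work.
criteria:
- id: bioterror
  label: Bioterrorism Potential
  question: Is the pathogen listed as a select agent (Lists A, B, or C)?
  source: As referenced by CDC website.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: severity
  label: Severity of Illness in Humans
  question: Is the case fatality rate for the pathogen/disease in humans greater than 10%?
  source: As referenced by WHO website or published literature specific to the country.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: economic
  label: Economic Burden of Disease
  question: Does the pathogen cause more than 10% mortality in the animal population or more than a 10% decrease in animal productivity?
  source: As referenced by OIE website or published literature specific to the country.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: collaborate
  label: Amenability to Collaborate
  question: Do human or animal health laboratories have diagnostic capacity available for the pathogen in Country X?
  source: Confirmation from Country X laboratory personnel.
  scale:
    kind: multinomial
    categories: [neither, at least one, both]
- id: epidemic
  label: Epidemic Potential
  question: Has the pathogen been detected in a new location or population (human or animal) within Country X or any bordering country within the past 5 years?
  source: Country X outbreak/surveillance data; confirmed reports to ProMED, WHO or OIE.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
diseases:
- Rabies
- Anthrax
- Brucellosis
- Bovine Tuberculosis
- Highly Pathogenic Avian Influenza
- Echinococcosis
- Leptospirosis
- Q Fever
- Rift Valley Fever
- Plague
- Human African Trypanosomiasis
- Leishmaniasis
- Toxoplasmosis
- Porcine Cysticercosis
- Ebola Virus Disease
- Lassa Fever
- Nipah Virus Infection
- West Nile Fever
- Crimean-Congo Haemorrhagic Fever
- Bacterial Food-Borne Zoonoses
metadata:
  purpose: Joint surveillance funding allocation between the human and animal health agencies of Country X
  participants: 10 (5 per agency)
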