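# Example criteria library: eight criteria commonly offered to stakeholder
# groups as a starting handout, each paired with one of its candidate
# categorical questions. Epidemic and pandemic potential are kept as
# separate criteria so each has exactly one question.
criteria:
- id: transmission
  label: Transmission potential between humans and animals
  question: Has the disease caused outbreaks in the country involving animals and humans within the last 5 years?
  source: Country outbreak records; ProMED reports.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: epidemic
  label: Epidemic potential in humans
  question: Has the disease caused epidemics in the past 5 years?
  source: WHO website; published literature.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: pandemic
  label: Pandemic potential in humans
  question: Has the disease caused pandemics in the past 5 years?
  source: WHO website; published literature.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: bioterrorism
  label: Bioterrorism potential
  question: Is the disease listed as a select agent (Lists A, B, and C)?
  source: CDC select agent lists.
  scale:
    kind: binomial
    categories: ['no', 'yes']
    full_score_category: 'yes'
- id: collaborate
  label: Amenability to collaborate / collaboration already established
  question: Do both the Ministry of Health (MoH) and Ministry of Agriculture (MoA) have surveillance/control measures for the disease?
  source: Ministry programme inventories.
  scale:
    kind: multinomial
    categories: [neither, either MoH or MoA, both MoH and MoA]
- id: economic
  label: Economic burden of disease
  question: What is the disease case fatality rate in animals without treatment?
  source: OIE website; published literature.
  scale:
    kind: multinomial
    categories: [0-1%, '>1-10%', '>10-25%', '>25%']
- id: severity
  label: Severity of illness in humans
  question: What is the disease case fatality rate in humans without treatment?
  source: WHO website; published literature.
  scale:
    kind: multinomial
    categories: [0-1%, '>1-10%', '>10%']
- id: prevention
  label: Ability to prevent/control the disease in the country
  question: Is the disease listed in country-specific surveillance programs for humans or animals?
  source: National surveillance programme listings.
  scale:
    kind: multinomial
    categories: [neither, human or animal, both human and animal]
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
  purpose: Example criteria library for configuring a prioritization exercise
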