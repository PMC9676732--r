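# Topographical cancer-site vocabulary (35 exhaustive, mutually exclusive
# labels, GLOBOCAN-style) and their mapping to the 14 reporting groups.
# Editable: the grouping of individual sites is a reconstruction by group
# label; edit freely as long as every site maps to exactly one group.
groups:
  Breast:
    - Breast
  Cervical:
    - Cervix uteri
  Upper gastrointestinal:
    - Oesophagus
    - Stomach
    - Small intestine
    - Liver
    - Gallbladder
    - Pancreas
  Hematological:
    - Hodgkin lymphoma
    - Non-Hodgkin lymphoma
    - Multiple myeloma
    - Leukaemia
  Other female-specific:
    - Vulva
    - Vagina
    - Corpus uteri
    - Ovary
  Lower gastrointestinal:
    - Colon
    - Rectum
    - Anus
  Respiratory:
    - Trachea, bronchus and lung
    - Mesothelioma
  Brain and nervous system:
    - Brain, central nervous system
  Head and Neck:
    - Lip, oral cavity
    - Salivary glands
    - Oropharynx
    - Nasopharynx
    - Hypopharynx
    - Larynx
  Genitourinary:
    - Kidney
    - Bladder
  Skin cancer:
    - Melanoma of skin
    - Non-melanoma skin
  Kaposi Sarcoma:
    - Kaposi sarcoma
  Thyroid:
    - Thyroid
  Other:
    - Other and unspecified
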