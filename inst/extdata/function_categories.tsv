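major	minor
Metabolism	Energy
Metabolism	Photosynthesis
Metabolism	E-transfer
Metabolism	Amino acids m/tr
Metabolism	Nitrogen m/tr
Metabolism	Nucleotide m/tr
Metabolism	Carbohydrate m/tr
Metabolism	Polysaccharide m/tr
Metabolism	Storage
Metabolism	Coenzyme m/tr
Metabolism	Lipid m/tr
Metabolism	Cell envelope m/tr
Metabolism	Secondary metabolism
Metabolism	Redox
Metabolism	Transferases
Metabolism	Other enzymes
Information	Chromatin structure
Information	Translation
Information	Transcription
Information	DNA replication/repair
Information	RNA processing
Information	Nuclear structure
Intracellular processes	Cell cycle
Intracellular processes	Apoptosis
Intracellular processes	Phospholipid m/tr
Intracellular processes	Cell motility
Intracellular processes	Trafficking/secretion
Intracellular processes	Protein modification
Intracellular processes	Proteases
Intracellular processes	Ion m/tr
Intracellular processes	Transport
Regulation	RNA binding, m/tr
Regulation	DNA-binding
Regulation	Kinases/phosphatases
Regulation	Signal transduction
Regulation	Other regulatory function
Regulation	Receptor activity
General	Small molecule binding
General	Ion binding
General	Lipid/membrane binding
General	Ligand binding
General	General
General	Protein interaction
General	Structural protein
Other	Unknown functions
Other	Viral proteins
Extracellular processes	Cell adhesion
Extracellular processes	Immune response
Extracellular processes	Blood clotting
Extracellular processes	Toxins/defense
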