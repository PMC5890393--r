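module	gene_a	gene_b	description
AmqTCONS_00003141	Aqu2.1.43387_001	scigt010895	mitochondrial dicarboxylate carrier
AmqTCONS_00003141	Aqu2.1.41074_001	scigt017797	protein disulfide-isomerase a5-like
AmqTCONS_00003141	Aqu2.1.30885_001	scigt001771	sh3 and px domain-containing protein 2a-like
AmqTCONS_00003141	Aqu2.1.36626_001	scigt016036	adp-ribosylation factor gtpase-activating protein 2-like
AmqTCONS_00003141	Aqu2.1.30885_001	scigt018255	sh3 and px domain-containing protein 2a-like
AmqTCONS_00003141	Aqu2.1.41568_001	scigt000612	tgf-beta receptor type-1
AmqTCONS_00003141	Aqu2.1.41568_001	scigt008994	tgf-beta receptor type-1
AmqTCONS_00001337-9	Aqu2.1.43947_001	scigt017951	arylsulfatase b-like
AmqTCONS_00001337-9	Aqu2.1.24502_001	scigt017951	arylsulfatase b-like
AmqTCONS_00001337-9	Aqu2.1.39727_001	scigt017951	arylsulfatase
AmqTCONS_00001337-9	Aqu2.1.41029_001	scigt017951	arylsulfatase
AmqTCONS_00001337-9	Aqu2.1.37909_001	scigt017951	sulfatase
AmqTCONS_00001337-9	Aqu2.1.37909_001	scigt014545	sulfatase
AmqTCONS_00001337-9	Aqu2.1.41029_001	scigt014545	arylsulfatase
AmqTCONS_00001337-9	Aqu2.1.39727_001	scigt014545	arylsulfatase
AmqTCONS_00001337-9	Aqu2.1.32274_001	scigt017997	usherin
AmqTCONS_00001337-9	Aqu2.1.28087_001	scigt020120	lysosomal alpha-glucosidase-like isoform x2
AmqTCONS_00001337-9	Aqu2.1.35119_001	scigt020423	filamin-c-like isoform x3
AmqTCONS_00001337-9	Aqu2.1.32241_001	scigt000557	myosin-i heavy chain
AmqTCONS_00001337-9	Aqu2.1.36394_001	scigt008273	deleted in malignant brain tumors 1
AmqTCONS_00001337-9	Aqu2.1.42755_001	scigt017951	arylsulfatase b-like
AmqTCONS_00003502	Aqu2.1.44676_001	scigt000138	actin family protein
AmqTCONS_00003502	Aqu2.1.38758_001	scigt001771	tyrosine-protein kinase lck
AmqTCONS_00003502	Aqu2.1.44676_001	scigt005362	actin family protein
AmqTCONS_00003502	Aqu2.1.40987_001	scigt004922	unconventional myosin-viia
AmqTCONS_00003502	Aqu2.1.24982_001	scigt008792	adenylyl cyclase-associated protein 1
AmqTCONS_00003502	Aqu2.1.40987_001	scigt012572	unconventional myosin-viia
AmqTCONS_00003502	Aqu2.1.32914_001	scigt014349	pleckstrin homology domain-containing family g member 1-like
AmqTCONS_00003502	Aqu2.1.28519_001	scigt016045	ap-2 complex subunit alpha-1-like
AmqTCONS_00003502	Aqu2.1.43989_001	scigt020995	protein plant cadmium resistance 3-like
AmqTCONS_00003502	Aqu2.1.44676_001	scigt021992	actin family protein
AmqTCONS_00003502	Aqu2.1.44676_001	scigt022018	actin family protein
AmqTCONS_00003502	Aqu2.1.40987_001	scigt025009	unconventional myosin-viia
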