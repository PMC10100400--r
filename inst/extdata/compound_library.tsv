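compound_id	name	formula
M001	cytosine	C4H5N3O
M002	phosphoric acid	H3PO4
M003	purine	C5H4N4
M004	xanthine	C5H4N4O2
M005	8-hydroxy-7-methylguanine	C6H7N5O2
M006	indole	C8H7N
M007	phenylethanolamine	C8H11NO
M008	adenine	C5H5N5
M009	L-tryptophan	C11H12N2O2
M010	L-kynurenine	C10H12N2O3
M011	kynurenic acid	C10H7NO3
M012	3-hydroxykynurenine	C10H12N2O4
M013	3-hydroxyanthranilic acid	C7H7NO3
M014	anthranilic acid	C7H7NO2
M015	quinolinic acid	C7H5NO4
M016	picolinic acid	C6H5NO2
M017	serotonin	C10H12N2O
M018	5-hydroxy-L-tryptophan	C11H12N2O3
M019	tryptamine	C10H12N2
M020	N-acetylserotonin	C12H14N2O2
M021	melatonin	C13H16N2O2
M022	indole-3-acetaldehyde	C10H9NO
M023	indole-3-acetic acid	C10H9NO2
M024	indole-3-pyruvic acid	C11H9NO3
M025	xanthurenic acid	C10H7NO4
M026	4,6-dihydroxyquinoline	C9H7NO2
M027	2-aminomuconate semialdehyde	C6H7NO3
M028	5-hydroxyindoleacetic acid	C10H9NO3
M029	N-formylkynurenine	C11H12N2O4
M030	kynuramine	C9H12N2O
M031	5-methoxytryptamine	C11H14N2O
M032	2-aminomuconic acid	C6H7NO4
M033	nicotinic acid	C6H5NO2
M034	indole-3-lactic acid	C11H11NO3
M035	nicotinamide	C6H6N2O
M036	3-methylindole	C9H9N
M037	glycine	C2H5NO2
M038	L-alanine	C3H7NO2
M039	L-serine	C3H7NO3
M040	L-proline	C5H9NO2
M041	L-valine	C5H11NO2
M042	L-threonine	C4H9NO3
M043	L-cysteine	C3H7NO2S
M044	L-leucine	C6H13NO2
M045	L-isoleucine	C6H13NO2
M046	L-asparagine	C4H8N2O3
M047	L-aspartic acid	C4H7NO4
M048	L-glutamine	C5H10N2O3
M049	L-glutamic acid	C5H9NO4
M050	L-lysine	C6H14N2O2
M051	L-methionine	C5H11NO2S
M052	L-histidine	C6H9N3O2
M053	L-phenylalanine	C9H11NO2
M054	L-arginine	C6H14N4O2
M055	L-tyrosine	C9H11NO3
M056	L-ornithine	C5H12N2O2
M057	L-citrulline	C6H13N3O3
M058	creatine	C4H9N3O2
M059	creatinine	C4H7N3O
M060	4-hydroxyproline	C5H9NO3
M061	agmatine	C5H14N4
M062	putrescine	C4H12N2
M063	spermidine	C7H19N3
M064	spermine	C10H26N4
M065	L-glutamate 5-semialdehyde	C5H9NO3
M066	N-acetylornithine	C7H14N2O3
M067	guanidinoacetic acid	C3H7N3O2
M068	1-pyrroline-5-carboxylic acid	C5H7NO2
M069	sarcosine	C3H7NO2
M070	urea	CH4N2O
M071	N-acetylputrescine	C6H14N2O
M072	5-aminovaleric acid	C5H11NO2
M073	dopamine	C8H11NO2
M074	levodopa	C9H11NO4
M075	norepinephrine	C8H11NO3
M076	epinephrine	C9H13NO3
M077	3-methoxytyramine	C9H13NO2
M078	tyramine	C8H11NO
M079	homovanillic acid	C9H10O4
M080	vanillylmandelic acid	C9H10O5
M081	metanephrine	C10H15NO3
M082	4-hydroxyphenylpyruvic acid	C9H8O4
M083	homogentisic acid	C8H8O4
M084	4-fumarylacetoacetic acid	C8H8O6
M085	4-hydroxyphenylacetic acid	C8H8O3
M086	p-cresol	C7H8O
M087	histamine	C5H9N3
M088	urocanic acid	C6H6N2O2
M089	imidazoleacetic acid	C5H6N2O2
M090	carnosine	C9H14N4O3
M091	1-methylhistidine	C7H11N3O2
M092	N-formimino-L-glutamic acid	C6H10N2O4
M093	3-methylhistidine	C7H11N3O2
M094	hypoxanthine	C5H4N4O
M095	guanine	C5H5N5O
M096	uric acid	C5H4N4O3
M097	uracil	C4H4N2O2
M098	thymine	C5H6N2O2
M099	orotic acid	C5H4N2O4
M100	inosine	C10H12N4O5
M101	adenosine	C10H13N5O4
M102	guanosine	C10H13N5O5
M103	adenosine monophosphate	C10H14N5O7P
M104	guanosine monophosphate	C10H14N5O8P
M105	uridine monophosphate	C9H13N2O9P
M106	cytidine monophosphate	C9H14N3O8P
M107	cytidine	C9H13N3O5
M108	uridine	C9H12N2O6
M109	thymidine	C10H14N2O5
M110	xanthosine	C10H12N4O6
M111	allantoin	C4H6N4O3
M112	caffeine	C8H10N4O2
M113	theobromine	C7H8N4O2
M114	7-methylguanine	C6H7N5O
M115	pseudouridine	C9H12N2O6
M116	D-glucose	C6H12O6
M117	glucose 6-phosphate	C6H13O9P
M118	fructose 1,6-bisphosphate	C6H14O12P2
M119	glyceraldehyde 3-phosphate	C3H7O6P
M120	3-phosphoglyceric acid	C3H7O7P
M121	phosphoenolpyruvic acid	C3H5O6P
M122	pyruvic acid	C3H4O3
M123	L-lactic acid	C3H6O3
M124	citric acid	C6H8O7
M125	cis-aconitic acid	C6H6O6
M126	alpha-ketoglutaric acid	C5H6O5
M127	succinic acid	C4H6O4
M128	fumaric acid	C4H4O4
M129	L-malic acid	C4H6O5
M130	oxaloacetic acid	C4H4O5
M131	glycerol	C3H8O3
M132	glycerol 3-phosphate	C3H9O6P
M133	ribose 5-phosphate	C5H11O8P
M134	sedoheptulose 7-phosphate	C7H15O10P
M135	6-phosphogluconic acid	C6H13O10P
M136	erythrose 4-phosphate	C4H9O7P
M137	dihydroxyacetone phosphate	C3H7O6P
M138	D-ribose	C5H10O5
M139	2-hydroxyglutaric acid	C5H8O5
M140	palmitic acid	C16H32O2
M141	stearic acid	C18H36O2
M142	oleic acid	C18H34O2
M143	linoleic acid	C18H32O2
M144	arachidonic acid	C20H32O2
M145	myristic acid	C14H28O2
M146	lauric acid	C12H24O2
M147	palmitoleic acid	C16H30O2
M148	docosahexaenoic acid	C22H32O2
M149	eicosapentaenoic acid	C20H30O2
M150	caprylic acid	C8H16O2
M151	capric acid	C10H20O2
M152	butyric acid	C4H8O2
M153	hexanoic acid	C6H12O2
M154	azelaic acid	C9H16O4
M155	sebacic acid	C10H18O4
M156	glycerophosphocholine	C8H20NO6P
M157	phosphocholine	C5H14NO4P
M158	choline	C5H13NO
M159	L-carnitine	C7H15NO3
M160	acetylcarnitine	C9H17NO4
M161	ethanolamine	C2H7NO
M162	phosphoethanolamine	C2H8NO4P
M163	sphingosine	C18H37NO2
M164	propionylcarnitine	C10H19NO4
M165	butyrylcarnitine	C11H21NO4
M166	isovalerylcarnitine	C12H23NO4
M167	hexanoylcarnitine	C13H25NO4
M168	octanoylcarnitine	C15H29NO4
M169	decanoylcarnitine	C17H33NO4
M170	lauroylcarnitine	C19H37NO4
M171	myristoylcarnitine	C21H41NO4
M172	palmitoylcarnitine	C23H45NO4
M173	oleoylcarnitine	C25H47NO4
M174	acetic acid	C2H4O2
M175	formic acid	CH2O2
M176	propionic acid	C3H6O2
M177	oxalic acid	C2H2O4
M178	malonic acid	C3H4O4
M179	glutaric acid	C5H8O4
M180	adipic acid	C6H10O4
M181	benzoic acid	C7H6O2
M182	hippuric acid	C9H9NO3
M183	salicylic acid	C7H6O3
M184	4-hydroxybenzoic acid	C7H6O3
M185	phenyllactic acid	C9H10O3
M186	phenylpyruvic acid	C9H8O3
M187	catechol	C6H6O2
M188	ascorbic acid	C6H8O6
M189	pantothenic acid	C9H17NO5
M190	riboflavin	C17H20N4O6
M191	pyridoxine	C8H11NO3
M192	pyridoxal	C8H9NO3
M193	biotin	C10H16N2O3S
M194	folic acid	C19H19N7O6
M195	taurine	C2H7NO3S
M196	hypotaurine	C2H7NO2S
M197	cysteic acid	C3H7NO5S
M198	glutathione	C10H17N3O6S
M199	glutathione disulfide	C20H32N6O12S2
M200	L-cystine	C6H12N2O4S2
M201	methionine sulfoxide	C5H11NO3S
M202	S-adenosylhomocysteine	C14H20N6O5S
M203	homocysteine	C4H9NO2S
M204	betaine	C5H11NO2
M205	dimethylglycine	C4H9NO2
M206	gamma-aminobutyric acid	C4H9NO2
M207	beta-alanine	C3H7NO2
M208	N-acetylaspartic acid	C6H9NO5
M209	N-acetylglutamic acid	C7H11NO5
M210	2-aminoadipic acid	C6H11NO4
M211	pipecolic acid	C6H11NO2
M212	saccharopine	C11H20N2O6
M213	mevalonic acid	C6H12O4
M214	trehalose	C12H22O11
M215	sucrose	C12H22O11
M216	myo-inositol	C6H12O6
M217	D-mannitol	C6H14O6
M218	D-xylose	C5H10O5
M219	L-fucose	C6H12O5
M220	D-glucuronic acid	C6H10O7
M221	N-acetylglucosamine	C8H15NO6
M222	N-acetylneuraminic acid	C11H19NO9
M223	shikimic acid	C7H10O5
M224	quinic acid	C7H12O6
M225	chorismic acid	C10H10O6
M226	cholesterol	C27H46O
M227	cholesterol sulfate	C27H46O4S
M228	cholic acid	C24H40O5
M229	chenodeoxycholic acid	C24H40O4
M230	taurocholic acid	C26H45NO7S
M231	bilirubin	C33H36N4O6
M232	biliverdin	C33H34N4O6
M233	maltose	C12H22O11
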