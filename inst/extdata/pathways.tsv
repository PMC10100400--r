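pathway_id	pathway_name	compound_id	formula
PW_TRP	tryptophan metabolism	M006	C8H7N
PW_TRP	tryptophan metabolism	M009	C11H12N2O2
PW_TRP	tryptophan metabolism	M010	C10H12N2O3
PW_TRP	tryptophan metabolism	M011	C10H7NO3
PW_TRP	tryptophan metabolism	M012	C10H12N2O4
PW_TRP	tryptophan metabolism	M013	C7H7NO3
PW_TRP	tryptophan metabolism	M014	C7H7NO2
PW_TRP	tryptophan metabolism	M015	C7H5NO4
PW_TRP	tryptophan metabolism	M016	C6H5NO2
PW_TRP	tryptophan metabolism	M017	C10H12N2O
PW_TRP	tryptophan metabolism	M018	C11H12N2O3
PW_TRP	tryptophan metabolism	M019	C10H12N2
PW_TRP	tryptophan metabolism	M020	C12H14N2O2
PW_TRP	tryptophan metabolism	M021	C13H16N2O2
PW_TRP	tryptophan metabolism	M022	C10H9NO
PW_TRP	tryptophan metabolism	M023	C10H9NO2
PW_TRP	tryptophan metabolism	M024	C11H9NO3
PW_TRP	tryptophan metabolism	M025	C10H7NO4
PW_TRP	tryptophan metabolism	M026	C9H7NO2
PW_TRP	tryptophan metabolism	M027	C6H7NO3
PW_TRP	tryptophan metabolism	M028	C10H9NO3
PW_TRP	tryptophan metabolism	M029	C11H12N2O4
PW_TRP	tryptophan metabolism	M030	C9H12N2O
PW_TRP	tryptophan metabolism	M031	C11H14N2O
PW_TRP	tryptophan metabolism	M032	C6H7NO4
PW_TRP	tryptophan metabolism	M033	C6H5NO2
PW_TRP	tryptophan metabolism	M034	C11H11NO3
PW_TRP	tryptophan metabolism	M035	C6H6N2O
PW_TRP	tryptophan metabolism	M036	C9H9N
PW_ARGPRO	arginine and proline metabolism	M040	C5H9NO2
PW_ARGPRO	arginine and proline metabolism	M047	C4H7NO4
PW_ARGPRO	arginine and proline metabolism	M048	C5H10N2O3
PW_ARGPRO	arginine and proline metabolism	M049	C5H9NO4
PW_ARGPRO	arginine and proline metabolism	M054	C6H14N4O2
PW_ARGPRO	arginine and proline metabolism	M056	C5H12N2O2
PW_ARGPRO	arginine and proline metabolism	M057	C6H13N3O3
PW_ARGPRO	arginine and proline metabolism	M058	C4H9N3O2
PW_ARGPRO	arginine and proline metabolism	M059	C4H7N3O
PW_ARGPRO	arginine and proline metabolism	M060	C5H9NO3
PW_ARGPRO	arginine and proline metabolism	M061	C5H14N4
PW_ARGPRO	arginine and proline metabolism	M062	C4H12N2
PW_ARGPRO	arginine and proline metabolism	M063	C7H19N3
PW_ARGPRO	arginine and proline metabolism	M064	C10H26N4
PW_ARGPRO	arginine and proline metabolism	M065	C5H9NO3
PW_ARGPRO	arginine and proline metabolism	M066	C7H14N2O3
PW_ARGPRO	arginine and proline metabolism	M067	C3H7N3O2
PW_ARGPRO	arginine and proline metabolism	M068	C5H7NO2
PW_ARGPRO	arginine and proline metabolism	M069	C3H7NO2
PW_ARGPRO	arginine and proline metabolism	M070	CH4N2O
PW_ARGPRO	arginine and proline metabolism	M071	C6H14N2O
PW_ARGPRO	arginine and proline metabolism	M072	C5H11NO2
PW_TYR	tyrosine metabolism	M007	C8H11NO
PW_TYR	tyrosine metabolism	M053	C9H11NO2
PW_TYR	tyrosine metabolism	M055	C9H11NO3
PW_TYR	tyrosine metabolism	M073	C8H11NO2
PW_TYR	tyrosine metabolism	M074	C9H11NO4
PW_TYR	tyrosine metabolism	M075	C8H11NO3
PW_TYR	tyrosine metabolism	M076	C9H13NO3
PW_TYR	tyrosine metabolism	M077	C9H13NO2
PW_TYR	tyrosine metabolism	M078	C8H11NO
PW_TYR	tyrosine metabolism	M079	C9H10O4
PW_TYR	tyrosine metabolism	M080	C9H10O5
PW_TYR	tyrosine metabolism	M081	C10H15NO3
PW_TYR	tyrosine metabolism	M082	C9H8O4
PW_TYR	tyrosine metabolism	M083	C8H8O4
PW_TYR	tyrosine metabolism	M084	C8H8O6
PW_TYR	tyrosine metabolism	M085	C8H8O3
PW_TYR	tyrosine metabolism	M086	C7H8O
PW_TYR	tyrosine metabolism	M128	C4H4O4
PW_HIS	histidine metabolism	M052	C6H9N3O2
PW_HIS	histidine metabolism	M087	C5H9N3
PW_HIS	histidine metabolism	M088	C6H6N2O2
PW_HIS	histidine metabolism	M089	C5H6N2O2
PW_HIS	histidine metabolism	M090	C9H14N4O3
PW_HIS	histidine metabolism	M091	C7H11N3O2
PW_HIS	histidine metabolism	M092	C6H10N2O4
PW_HIS	histidine metabolism	M093	C7H11N3O2
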