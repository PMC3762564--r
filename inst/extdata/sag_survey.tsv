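sample	phenotype	genotype
dog001	normal	hom_ref
dog002	normal	hom_ref
dog003	normal	hom_ref
dog004	normal	hom_ref
dog005	normal	hom_ref
dog006	normal	hom_ref
dog007	normal	hom_ref
dog008	normal	het
dog009	normal	het
dog010	normal	het
dog011	normal	het
dog012	normal	het
dog013	normal	het
dog014	normal	het
dog015	normal	het
dog016	normal	het
dog017	normal	het
dog018	normal	hom_alt
dog019	affected	hom_ref
dog020	affected	hom_ref
dog021	affected	hom_alt
dog022	affected	hom_alt
dog023	affected	hom_alt
dog024	affected	hom_alt
dog025	affected	hom_alt
dog026	affected	hom_alt
dog027	affected	hom_alt
dog028	affected	hom_alt
dog029	affected	hom_alt
dog030	affected	hom_alt
dog031	affected	hom_alt
dog032	affected	hom_alt
dog033	affected	hom_alt
dog034	affected	hom_alt
dog035	affected	hom_alt
dog036	affected	hom_alt
dog037	affected	hom_alt
dog038	suspicious	het
dog039	suspicious	het
dog040	suspicious	hom_alt
dog041	suspicious	hom_alt
dog042	suspicious	hom_alt
dog043	suspicious	hom_alt
dog044	unknown	hom_ref
dog045	unknown	hom_ref
dog046	unknown	hom_ref
dog047	unknown	hom_ref
dog048	unknown	hom_ref
dog049	unknown	hom_ref
dog050	unknown	hom_ref
dog051	unknown	hom_ref
dog052	unknown	hom_ref
dog053	unknown	hom_ref
dog054	unknown	hom_ref
dog055	unknown	hom_ref
dog056	unknown	hom_ref
dog057	unknown	hom_ref
dog058	unknown	hom_ref
dog059	unknown	hom_ref
dog060	unknown	het
dog061	unknown	het
dog062	unknown	het
dog063	unknown	het
dog064	unknown	het
dog065	unknown	het
dog066	unknown	het
dog067	unknown	het
dog068	unknown	het
dog069	unknown	het
dog070	unknown	het
dog071	unknown	het
dog072	unknown	het
dog073	unknown	het
dog074	unknown	het
dog075	unknown	het
dog076	unknown	het
dog077	unknown	het
dog078	unknown	het
dog079	unknown	hom_alt
dog080	unknown	hom_alt
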