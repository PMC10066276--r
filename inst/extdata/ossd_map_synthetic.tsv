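accession	category
OMB001	oral_microbiome
OMB002	oral_microbiome
OMB003	oral_microbiome
OMB004	oral_microbiome
OMB005	oral_microbiome
OMB006	oral_microbiome
OMB007	oral_microbiome
OMB008	oral_microbiome
OMB009	oral_microbiome
OMB010	oral_microbiome
OMB011	oral_microbiome
OMB012	oral_microbiome
OMB013	oral_microbiome
OMB014	oral_microbiome
OMB015	oral_microbiome
OMB016	oral_microbiome
OMB017	oral_microbiome
OMB018	oral_microbiome
OMB019	oral_microbiome
OMB020	oral_microbiome
OMB021	oral_microbiome
OMB022	oral_microbiome
OMB023	oral_microbiome
OMB024	oral_microbiome
OMB025	oral_microbiome
OMB026	oral_microbiome
OMB027	oral_microbiome
OMB028	oral_microbiome
OMB029	oral_microbiome
OMB030	oral_microbiome
OMB031	oral_microbiome
OMB032	oral_microbiome
OMB033	oral_microbiome
OMB034	oral_microbiome
OMB035	oral_microbiome
OMB036	oral_microbiome
OMB037	oral_microbiome
OMB038	oral_microbiome
OMB039	oral_microbiome
OMB040	oral_microbiome
IMM001	immune
IMM002	immune
IMM003	immune
IMM004	immune
IMM005	immune
IMM006	immune
IMM007	immune
IMM008	immune
IMM009	immune
IMM010	immune
LABK01	lab_contaminant
LABK02	lab_contaminant
LABK03	lab_contaminant
LABK04	lab_contaminant
LABT01	lab_contaminant
ENVC01	env_contaminant
ENVC02	env_contaminant
ENVC03	env_contaminant
ENVC04	env_contaminant
ENVC05	env_contaminant
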