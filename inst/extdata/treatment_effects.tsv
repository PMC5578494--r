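treatment	trait	effect	effect_type
pollen_rna	developmental_time_days	0.49	absolute
pollen_rna	weight	-14.81	percent
pollen_rna	length	-6.55	percent
pollen_rna	ovarioles	-21	absolute
mirna_pool	developmental_time_days	0.58	absolute
mirna_pool	weight	-10.27	percent
mirna_pool	length	-4.01	percent
mirna_pool	ovarioles	-38	absolute
mir162a	developmental_time_days	0.17	absolute
mir162a	weight	-7.87	percent
mir162a	length	-4.49	percent
mir162a	ovarioles	-29	absolute
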