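query_id	true_short_ik	parent_mass	molecular_formula	kingdom	phylum	class	order	family	genus	species
1772	OUTYMWDDJORZOH	342.167		Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Glaucium	Glaucium grandiflorum
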