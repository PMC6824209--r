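query_id	candidate_short_ik	molecule_name	raw_score	normalized_score	initial_rank	tool	kingdom	phylum	class	order	family	genus	species
1772	OUTYMWDDJORZOH	Predicentrine	0.36	0.23	9	isdb	Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Glaucium	Glaucium oxylobum
1772	QELDJEKNFOQJOY	Isocorydine	0.34	0.22	11	isdb	Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Glaucium	
1772	KDFKJOFJHSVROC	Isocorypalmine	0.3	0.14	28	isdb	Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Glaucium	Glaucium fimbrilligerum
1772	JADHMUPTWPBTMT	Secosarcocapnidine Me ether, N-De-Me	0.4	0.32	1	isdb	Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Sarcocapnos	Sarcocapnos crassifolia
1772	WNBUTZHPPULVTP	Secocularidine Me ether, N-de-Me	0.39	0.29	2	isdb	Plantae	Tracheophyta	Magnoliopsida	Ranunculales	Papaveraceae	Ceratocapnos	Ceratocapnos claviculata
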