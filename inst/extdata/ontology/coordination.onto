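MODULE	coordination
IMPORT	core
CONCEPT	coord:ActionCommunication
LABEL	pref	fr	action de communication auprès du réseau
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueActionCoordination
CONCEPT	coord:Coordinateur
LABEL	alt	fr	COORDINATEUR SLA
LABEL	pref	fr	coordinateur sla
PARENT	core:Agent	asserted
CONCEPT	coord:DemandeRechercheProfessionnel
LABEL	pref	en	request to find a healthcare professional
LABEL	pref	fr	demande de recherche de professionnel
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueActionCoordination
CONCEPT	coord:DemandeSejourRepit
LABEL	pref	en	request for respite care
LABEL	pref	fr	demande de séjour de répit
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEpuisement
CONCEPT	coord:EvaluationBesoins
LABEL	pref	fr	évaluation des besoins
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueActionCoordination
CONCEPT	coord:PropositionSejourRepit
LABEL	pref	en	respite care proposal
LABEL	pref	fr	proposition de séjour de répit
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEpuisement
CONCEPT	coord:RechercheProfessionnel
LABEL	pref	en	search for a healthcare professional
LABEL	pref	fr	recherche de professionnel de santé
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueActionCoordination
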