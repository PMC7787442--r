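MODULE	core
PROPERTY	prop:aPourThematique
LABEL	pref	en	has theme
LABEL	pref	fr	a pour thématique
CONCEPT	core:Agent
LABEL	pref	fr	agent
PARENT	core:Entite	asserted
CONCEPT	core:Entite
LABEL	pref	fr	entité
CONCEPT	core:ObjetPhysique
LABEL	pref	fr	objet physique
PARENT	core:Entite	asserted
CONCEPT	core:Processus
LABEL	pref	fr	processus
PARENT	core:Entite	asserted
CONCEPT	core:Thematique
LABEL	pref	fr	thématique
PARENT	core:Entite	asserted
CONCEPT	core:ThematiqueActionCoordination
LABEL	pref	fr	thématique action de coordination
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueAideHumaine
LABEL	pref	fr	thématique aide humaine
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueAideSociale
LABEL	pref	fr	thématique aide sociale
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueAideTechnique
LABEL	pref	fr	thématique aide technique
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueEpuisement
LABEL	pref	fr	thématique épuisement
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueEtatCognitif
LABEL	pref	fr	thématique état cognitif
PARENT	core:Thematique	asserted
CONCEPT	core:ThematiqueEtatMoteur
LABEL	pref	fr	thématique état moteur
PARENT	core:Thematique	asserted
DEFINED	core:ActionCoordination
LABEL	pref	en	coordination action
LABEL	pref	fr	action de coordination
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueActionCoordination
DEFINED	core:DomaineAideHumaine
LABEL	pref	en	field of human help
LABEL	pref	fr	domaine de l'aide humaine
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideHumaine
DEFINED	core:DomaineAideSociale
LABEL	pref	en	area of need and request for social help
LABEL	pref	fr	domaine du besoin et de la demande d'aide sociale
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideSociale
DEFINED	core:DomaineAideTechnique
LABEL	pref	en	field of technical aids
LABEL	pref	fr	domaine de l'aide technique
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideTechnique
DEFINED	core:DomaineEpuisement
LABEL	pref	en	field of exhaustion
LABEL	pref	fr	domaine de l'épuisement
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEpuisement
DEFINED	core:EtatCognitif
LABEL	pref	en	cognitive state
LABEL	pref	fr	état cognitif
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatCognitif
DEFINED	core:EtatMoteur
LABEL	pref	en	motor state
LABEL	pref	fr	état moteur
PARENT	core:Entite	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatMoteur
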