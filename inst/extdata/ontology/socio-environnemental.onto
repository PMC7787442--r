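MODULE	socio-environnemental
IMPORT	core
CONCEPT	soc:AideHumaine
LABEL	pref	fr	aide humaine
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideHumaine
CONCEPT	soc:AuxiliaireVie
LABEL	alt	fr	adv
LABEL	pref	fr	auxiliaire de vie
PARENT	core:Agent	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideHumaine
CONCEPT	soc:BesoinRepit
LABEL	pref	en	need for respite care
LABEL	pref	fr	besoin de répit
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEpuisement
CONCEPT	soc:DemandeAideSociale
LABEL	pref	fr	demande d'aide sociale
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideSociale
CONCEPT	soc:DossierMdph
LABEL	alt	fr	mdph
LABEL	pref	fr	dossier mdph
PARENT	core:ObjetPhysique	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideSociale
CONCEPT	soc:EpuisementAidant
LABEL	alt	fr	aidant épuisé
LABEL	pref	en	patient carer exhaustion
LABEL	pref	fr	épuisement de l'aidant
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEpuisement
CONCEPT	soc:Famille
LABEL	pref	fr	famille
PARENT	core:Agent	asserted
CONCEPT	soc:FauteuilRoulantElectrique
LABEL	alt	fr	fauteuil électrique
LABEL	alt	fr	FRE
LABEL	pref	en	electric wheelchair
LABEL	pref	fr	fauteuil roulant électrique
PARENT	core:ObjetPhysique	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideTechnique
CONCEPT	soc:LitMedicalise
LABEL	pref	fr	lit médicalisé
PARENT	core:ObjetPhysique	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideTechnique
CONCEPT	soc:Logement
LABEL	pref	fr	logement
PARENT	core:ObjetPhysique	asserted
CONCEPT	soc:SalleDeBain
LABEL	alt	fr	SDB
LABEL	pref	en	bathroom
LABEL	pref	fr	salle de bain
PARENT	core:ObjetPhysique	asserted
CONCEPT	soc:SyntheseVocale
LABEL	pref	fr	synthèse vocale
PARENT	core:ObjetPhysique	asserted
ASSERT	prop:aPourThematique	core:ThematiqueAideTechnique
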