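MODULE	medical
IMPORT	core
CONCEPT	med:AgentMedical
LABEL	pref	fr	agent médical
PARENT	core:Agent	asserted
CONCEPT	med:Chute
LABEL	pref	fr	chute
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatMoteur
CONCEPT	med:ChuteRepetee
LABEL	pref	fr	chutes répétées
PARENT	med:Chute	asserted
CONCEPT	med:Desorientation
LABEL	pref	fr	désorientation
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatCognitif
CONCEPT	med:Hospitalisation
LABEL	pref	fr	hospitalisation
PARENT	core:Processus	asserted
CONCEPT	med:Infirmier
LABEL	alt	fr	ide
LABEL	pref	fr	infirmier
PARENT	med:AgentMedical	asserted
CONCEPT	med:Kinesitherapeute
LABEL	alt	fr	kiné
LABEL	pref	fr	kinésithérapeute
PARENT	med:AgentMedical	asserted
CONCEPT	med:MedecinTraitant
LABEL	alt	fr	family doctor
LABEL	alt	fr	general practitioner
LABEL	alt	fr	mdt
LABEL	alt	fr	méd t
LABEL	alt	fr	med tt
LABEL	alt	fr	méd tt
LABEL	alt	fr	med ttt
LABEL	alt	fr	mt
LABEL	pref	en	general practitioner
LABEL	pref	fr	médecin traitant
PARENT	med:AgentMedical	asserted
CONCEPT	med:Neurologue
LABEL	pref	en	neurologist
LABEL	pref	fr	neurologue
PARENT	med:AgentMedical	asserted
CONCEPT	med:PerteMotricite
LABEL	pref	fr	perte de motricité
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatMoteur
CONCEPT	med:PriseEnCharge
LABEL	alt	fr	PEC
LABEL	pref	fr	prise en charge
PARENT	core:Processus	asserted
CONCEPT	med:ProfessionnelSante
LABEL	alt	fr	PROFESSIONNEL
LABEL	pref	fr	professionnel de santé
PARENT	med:AgentMedical	asserted
CONCEPT	med:TroubleCognitif
LABEL	alt	fr	tb cognitifs
LABEL	pref	fr	troubles cognitifs
PARENT	core:Processus	asserted
ASSERT	prop:aPourThematique	core:ThematiqueEtatCognitif
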