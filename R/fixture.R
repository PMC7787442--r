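# A small but complete five-module ontology (core + medical +
# socio-environmental + coordination + consolidation) used by the synthetic
# generator, the examples and the test suite. It exercises every structural
# feature the pipeline relies on: multilingual pref/alt labels, abbreviation
# variants (PEC, SDB, FRE), accent-only label variants, role placeholders,
# fully defined theme concepts, cross-module theme assertions, and an
# assertion-inheriting subclass.

fixture_core_module <- function() {
  m <- "MODULE\tcore
PROPERTY\tprop:aPourThematique
LABEL\tpref\tfr\ta pour thématique
LABEL\tpref\ten\thas theme
CONCEPT\tcore:Entite
LABEL\tpref\tfr\tentité
CONCEPT\tcore:Agent
LABEL\tpref\tfr\tagent
PARENT\tcore:Entite
CONCEPT\tcore:Processus
LABEL\tpref\tfr\tprocessus
PARENT\tcore:Entite
CONCEPT\tcore:ObjetPhysique
LABEL\tpref\tfr\tobjet physique
PARENT\tcore:Entite
CONCEPT\tcore:Thematique
LABEL\tpref\tfr\tthématique
PARENT\tcore:Entite
CONCEPT\tcore:ThematiqueEpuisement
LABEL\tpref\tfr\tthématique épuisement
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueAideTechnique
LABEL\tpref\tfr\tthématique aide technique
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueAideHumaine
LABEL\tpref\tfr\tthématique aide humaine
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueAideSociale
LABEL\tpref\tfr\tthématique aide sociale
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueEtatMoteur
LABEL\tpref\tfr\tthématique état moteur
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueEtatCognitif
LABEL\tpref\tfr\tthématique état cognitif
PARENT\tcore:Thematique
CONCEPT\tcore:ThematiqueActionCoordination
LABEL\tpref\tfr\tthématique action de coordination
PARENT\tcore:Thematique
DEFINED\tcore:DomaineEpuisement
LABEL\tpref\tfr\tdomaine de l'épuisement
LABEL\tpref\ten\tfield of exhaustion
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueEpuisement
DEFINED\tcore:DomaineAideTechnique
LABEL\tpref\tfr\tdomaine de l'aide technique
LABEL\tpref\ten\tfield of technical aids
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideTechnique
DEFINED\tcore:DomaineAideHumaine
LABEL\tpref\tfr\tdomaine de l'aide humaine
LABEL\tpref\ten\tfield of human help
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideHumaine
DEFINED\tcore:DomaineAideSociale
LABEL\tpref\tfr\tdomaine du besoin et de la demande d'aide sociale
LABEL\tpref\ten\tarea of need and request for social help
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideSociale
DEFINED\tcore:EtatMoteur
LABEL\tpref\tfr\tétat moteur
LABEL\tpref\ten\tmotor state
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatMoteur
DEFINED\tcore:EtatCognitif
LABEL\tpref\tfr\tétat cognitif
LABEL\tpref\ten\tcognitive state
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatCognitif
DEFINED\tcore:ActionCoordination
LABEL\tpref\tfr\taction de coordination
LABEL\tpref\ten\tcoordination action
PARENT\tcore:Entite
ASSERT\tprop:aPourThematique\tcore:ThematiqueActionCoordination"
  m
}

fixture_medical_module <- function() {
  "MODULE\tmedical
IMPORT\tcore
CONCEPT\tmed:AgentMedical
LABEL\tpref\tfr\tagent médical
PARENT\tcore:Agent
CONCEPT\tmed:MedecinTraitant
LABEL\tpref\tfr\tmédecin traitant
LABEL\tpref\ten\tgeneral practitioner
LABEL\talt\tfr\tmed tt
LABEL\talt\tfr\tmt
LABEL\talt\tfr\tfamily doctor
LABEL\talt\tfr\tmed ttt
LABEL\talt\tfr\tméd t
LABEL\talt\tfr\tméd tt
LABEL\talt\tfr\tgeneral practitioner
LABEL\talt\tfr\tmdt
PARENT\tmed:AgentMedical
CONCEPT\tmed:Neurologue
LABEL\tpref\tfr\tneurologue
LABEL\tpref\ten\tneurologist
PARENT\tmed:AgentMedical
CONCEPT\tmed:ProfessionnelSante
LABEL\tpref\tfr\tprofessionnel de santé
LABEL\talt\tfr\tPROFESSIONNEL
PARENT\tmed:AgentMedical
CONCEPT\tmed:Kinesitherapeute
LABEL\tpref\tfr\tkinésithérapeute
LABEL\talt\tfr\tkiné
PARENT\tmed:AgentMedical
CONCEPT\tmed:Infirmier
LABEL\tpref\tfr\tinfirmier
LABEL\talt\tfr\tide
PARENT\tmed:AgentMedical
CONCEPT\tmed:Chute
LABEL\tpref\tfr\tchute
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatMoteur
CONCEPT\tmed:ChuteRepetee
LABEL\tpref\tfr\tchutes répétées
PARENT\tmed:Chute
CONCEPT\tmed:PerteMotricite
LABEL\tpref\tfr\tperte de motricité
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatMoteur
CONCEPT\tmed:TroubleCognitif
LABEL\tpref\tfr\ttroubles cognitifs
LABEL\talt\tfr\ttb cognitifs
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatCognitif
CONCEPT\tmed:Desorientation
LABEL\tpref\tfr\tdésorientation
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEtatCognitif
CONCEPT\tmed:PriseEnCharge
LABEL\tpref\tfr\tprise en charge
LABEL\talt\tfr\tPEC
PARENT\tcore:Processus
CONCEPT\tmed:Hospitalisation
LABEL\tpref\tfr\thospitalisation
PARENT\tcore:Processus"
}

fixture_socio_module <- function() {
  "MODULE\tsocio-environnemental
IMPORT\tcore
CONCEPT\tsoc:EpuisementAidant
LABEL\tpref\tfr\tépuisement de l'aidant
LABEL\tpref\ten\tpatient carer exhaustion
LABEL\talt\tfr\taidant épuisé
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEpuisement
CONCEPT\tsoc:BesoinRepit
LABEL\tpref\tfr\tbesoin de répit
LABEL\tpref\ten\tneed for respite care
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEpuisement
CONCEPT\tsoc:FauteuilRoulantElectrique
LABEL\tpref\tfr\tfauteuil roulant électrique
LABEL\tpref\ten\telectric wheelchair
LABEL\talt\tfr\tFRE
LABEL\talt\tfr\tfauteuil électrique
PARENT\tcore:ObjetPhysique
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideTechnique
CONCEPT\tsoc:LitMedicalise
LABEL\tpref\tfr\tlit médicalisé
PARENT\tcore:ObjetPhysique
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideTechnique
CONCEPT\tsoc:SyntheseVocale
LABEL\tpref\tfr\tsynthèse vocale
PARENT\tcore:ObjetPhysique
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideTechnique
CONCEPT\tsoc:SalleDeBain
LABEL\tpref\tfr\tsalle de bain
LABEL\tpref\ten\tbathroom
LABEL\talt\tfr\tSDB
PARENT\tcore:ObjetPhysique
CONCEPT\tsoc:AideHumaine
LABEL\tpref\tfr\taide humaine
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideHumaine
CONCEPT\tsoc:AuxiliaireVie
LABEL\tpref\tfr\tauxiliaire de vie
LABEL\talt\tfr\tadv
PARENT\tcore:Agent
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideHumaine
CONCEPT\tsoc:DemandeAideSociale
LABEL\tpref\tfr\tdemande d'aide sociale
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideSociale
CONCEPT\tsoc:DossierMdph
LABEL\tpref\tfr\tdossier mdph
LABEL\talt\tfr\tmdph
PARENT\tcore:ObjetPhysique
ASSERT\tprop:aPourThematique\tcore:ThematiqueAideSociale
CONCEPT\tsoc:Famille
LABEL\tpref\tfr\tfamille
PARENT\tcore:Agent
CONCEPT\tsoc:Logement
LABEL\tpref\tfr\tlogement
PARENT\tcore:ObjetPhysique"
}

fixture_coordination_module <- function() {
  "MODULE\tcoordination
IMPORT\tcore
CONCEPT\tcoord:DemandeSejourRepit
LABEL\tpref\tfr\tdemande de séjour de répit
LABEL\tpref\ten\trequest for respite care
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEpuisement
CONCEPT\tcoord:PropositionSejourRepit
LABEL\tpref\tfr\tproposition de séjour de répit
LABEL\tpref\ten\trespite care proposal
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueEpuisement
CONCEPT\tcoord:Coordinateur
LABEL\tpref\tfr\tcoordinateur sla
LABEL\talt\tfr\tCOORDINATEUR SLA
PARENT\tcore:Agent
CONCEPT\tcoord:ActionCommunication
LABEL\tpref\tfr\taction de communication auprès du réseau
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueActionCoordination
CONCEPT\tcoord:RechercheProfessionnel
LABEL\tpref\tfr\trecherche de professionnel de santé
LABEL\tpref\ten\tsearch for a healthcare professional
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueActionCoordination
CONCEPT\tcoord:DemandeRechercheProfessionnel
LABEL\tpref\tfr\tdemande de recherche de professionnel
LABEL\tpref\ten\trequest to find a healthcare professional
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueActionCoordination
CONCEPT\tcoord:EvaluationBesoins
LABEL\tpref\tfr\tévaluation des besoins
PARENT\tcore:Processus
ASSERT\tprop:aPourThematique\tcore:ThematiqueActionCoordination"
}

fixture_consolidation_module <- function() {
  "MODULE\tconsolidation
IMPORT\tcore
IMPORT\tmedical
IMPORT\tsocio-environnemental
IMPORT\tcoordination"
}

#' The bundled fixture ontology modules
#'
#' Five small modules (core, medical, socio-environmental, coordination and
#' an empty consolidation module) mirroring the structure of a modular
#' care-pathway ontology, including the eight alternative spellings of
#' 'general practitioner', the PEC/SDB/FRE abbreviations, role placeholders
#' and the exhaustion theme shared across two domain modules.
#'
#' @return list of five `onto_module` objects.
#' @export
fixture_modules <- function() {
  texts <- list(fixture_core_module(), fixture_medical_module(),
                fixture_socio_module(), fixture_coordination_module(),
                fixture_consolidation_module())
  lapply(texts, function(tx) {
    f <- tempfile(fileext = ".onto")
    on.exit(unlink(f))
    con <- file(f, "wt", encoding = "UTF-8")
    writeLines(tx, con)
    close(con)
    load_module(f, format = "plaintext")
  })
}

#' The consolidated (and optionally reasoned) fixture ontology
#'
#' @param reasoned run [infer_defined_members()] on the result (default TRUE).
#' @return An `ontology`.
#' @export
fixture_ontology <- function(reasoned = TRUE) {
  ont <- consolidate(fixture_modules())
  if (reasoned) ont <- infer_defined_members(ont)
  ont
}
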