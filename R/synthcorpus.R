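# Seeded generator of a synthetic cohort: patient table, telegraphic
# French-like event documents with planted concept mentions, and gold
# standoff annotations, plus a truth record sufficient to recompute the
# expected counts. The documents are stylized template sentences, not
# natural language: matching is lexical, so realism beyond lexicon usage
# adds nothing testable.

#' Generator configuration
#'
#' Defaults encode the cohort structure the pipeline assumes: events per
#' patient lognormal matched to mean 33.6 and SD 32.13, rounded up to at
#' least one event; per-theme mention rates per event chosen so that
#' per-patient totals have the magnitude seen in coordination-network
#' cohorts (technical aids frequent, cognitive mentions rare, coordination
#' actions dominant); a planted positive effect of the latent motor
#' severity on the exhaustion mention rate.
#'
#' @param seed integer RNG seed; same seed, same config, same ontology give
#'   byte-identical outputs.
#' @param n_patients cohort size.
#' @param events_mean,events_sd target mean/SD of the per-patient event count.
#' @param theme_rates named numeric: expected mentions per event per theme;
#'   names must be fully-defined-concept IRIs of the ontology passed to
#'   [generate_cohort()].
#' @param abbrev_prob probability a planted mention uses an alternative
#'   (abbreviated) label rather than the preferred one.
#' @param misspell_rate probability a planted mention surface gets a
#'   single-character corruption (recorded in the truth bundle).
#' @param negation_rate probability a planted mention is wrapped in a
#'   negation template (gold flag set).
#' @param motor_exhaustion_beta planted log-rate effect of the latent motor
#'   severity (standard normal) on the exhaustion theme rate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 100L,
                       events_mean = 33.6, events_sd = 32.13,
                       theme_rates = NULL,
                       abbrev_prob = 0.5, misspell_rate = 0,
                       negation_rate = 0, motor_exhaustion_beta = 0.5) {
  stopifnot(abbrev_prob >= 0, abbrev_prob <= 1,
            misspell_rate >= 0, misspell_rate <= 1,
            negation_rate >= 0, negation_rate <= 1,
            n_patients >= 0, events_mean > 0, events_sd >= 0)
  if (is.null(theme_rates)) {
    theme_rates <- c(
      "core:DomaineEpuisement"    = 0.11,
      "core:DomaineAideTechnique" = 0.86,
      "core:DomaineAideHumaine"   = 0.11,
      "core:DomaineAideSociale"   = 0.11,
      "core:EtatMoteur"           = 0.13,
      "core:EtatCognitif"         = 0.015,
      "core:ActionCoordination"   = 2.2
    )
  }
  stopifnot(all(theme_rates >= 0), !is.null(names(theme_rates)))
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 events_mean = events_mean, events_sd = events_sd,
                 theme_rates = theme_rates, abbrev_prob = abbrev_prob,
                 misspell_rate = misspell_rate, negation_rate = negation_rate,
                 motor_exhaustion_beta = motor_exhaustion_beta,
                 language = "fr"),
            class = "sim_config")
}

# templates: sentence = prefix + surface + suffix; role templates carry their
# own role-concept mention. Template vocabulary is checked against the index
# at generation time so every lexicon match in a document is a planted one.
sim_intro_templates <- data.frame(
  prefix = c("Appel de ", "Transmission de ", "Message de "),
  suffix = c(" ce jour .", " au domicile .", " pour suivi ."),
  concept = c("med:ProfessionnelSante", "coord:Coordinateur", "med:Neurologue"),
  surface = c("PROFESSIONNEL", "COORDINATEUR SLA", "NEUROLOGUE"),
  stringsAsFactors = FALSE
)
sim_mention_templates <- data.frame(
  prefix = c("Point sur ", "Nouvelle demande concernant ", "Suivi ", "A prevoir : "),
  suffix = c(" ce jour .", " a traiter .", " en cours .", " rapidement ."),
  stringsAsFactors = FALSE
)
sim_negation_templates <- data.frame(
  prefix = c("Pas de ", "L'entourage ne souhaite pas "),
  suffix = c(" ce jour .", " pour le moment ."),
  stringsAsFactors = FALSE
)

# single-character edit: replace one letter of the longest word by a letter
# one off in the alphabet (never a no-op)
corrupt_surface <- function(surface, at, repl) {
  substr(surface, at, at) <- repl
  surface
}

#' Generate a synthetic cohort bundle
#'
#' Draws a patient table (sex, ages, disease form, follow-up, social status,
#' lifestyle, number of events), one document per event built from template
#' sentences with planted lexicon surfaces, and the gold standoff
#' annotations of the planted mentions. Abbreviation variants, misspellings
#' (applied only to planted mentions, so recall loss is attributable) and
#' negation wrappers are applied with the configured probabilities, all
#' recorded in the truth record. Every theme in `config$theme_rates` must
#' resolve to a fully defined concept of `ontology` whose member concepts
#' carry at least one French label.
#'
#' @param config a [sim_config()].
#' @param ontology a reasoned `ontology` (see [infer_defined_members()]).
#' @return list of class `gold_bundle`: `patients`, `docs` (with `text`),
#'   `gold` (standoff data frame with `corrupted` column), `truth`, `config`.
#' @export
generate_cohort <- function(config, ontology) {
  stopifnot(inherits(config, "sim_config"), inherits(ontology, "ontology"))
  if (!isTRUE(attr(ontology, "reasoned")))
    stop("generate_cohort needs a reasoned ontology", call. = FALSE)
  themes <- names(config$theme_rates)
  bad <- setdiff(themes, ontology$defined$iri)
  if (length(bad)) stop("theme(s) not defined concepts of the ontology: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  # member concepts per theme (proper members, not the defined class itself)
  lab <- ontology$labels[ontology$labels$lang == "fr", , drop = FALSE]
  pref_of <- split(lab$text[lab$kind == "pref"], lab$iri[lab$kind == "pref"])
  alt_of  <- split(lab$text[lab$kind == "alt"],  lab$iri[lab$kind == "alt"])
  members <- lapply(themes, function(th) {
    m <- setdiff(descendants(ontology, th), th)
    m <- m[m %in% names(pref_of)]    # only mentionable (labelled) members
    if (!length(m)) stop("theme without any labelled member concept: ", th, call. = FALSE)
    m
  })
  names(members) <- themes

  set.seed(config$seed)
  np <- config$n_patients
  patients <- draw_patients(np, config)

  empty_gold <- data.frame(doc_id = character(), start = integer(), end = integer(),
                           surface = character(), iri = character(), negated = logical(),
                           corrupted = logical(), stringsAsFactors = FALSE)
  if (np == 0L) {
    return(structure(list(patients = patients,
                          docs = data.frame(doc_id = character(), patient_id = character(),
                                            date = character(), text = character(),
                                            stringsAsFactors = FALSE),
                          gold = empty_gold,
                          truth = list(z_motor = numeric(), lambda = matrix(0, 0, length(themes),
                                                                            dimnames = list(NULL, themes)),
                                       beta = config$motor_exhaustion_beta,
                                       corrupted = empty_gold[0, ]),
                          config = config), class = "gold_bundle"))
  }

  # latent motor severity drives the motor theme and (planted effect) the
  # exhaustion theme
  z <- stats::rnorm(np)
  lambda <- matrix(rep(config$theme_rates, each = np), nrow = np,
                   dimnames = list(patients$patient_id, themes))
  if ("core:EtatMoteur" %in% themes)
    lambda[, "core:EtatMoteur"] <- lambda[, "core:EtatMoteur"] * exp(0.8 * z)
  if ("core:DomaineEpuisement" %in% themes)
    lambda[, "core:DomaineEpuisement"] <-
      lambda[, "core:DomaineEpuisement"] * exp(config$motor_exhaustion_beta * z)

  # events
  ev_patient <- rep(seq_len(np), times = patients$n_events)
  ne <- length(ev_patient)
  ev_seq <- sequence(patients$n_events)
  doc_id <- sprintf("%s_E%03d", patients$patient_id[ev_patient], ev_seq)

  # intro (role) mention, one per event
  it <- sample.int(nrow(sim_intro_templates), ne, replace = TRUE)
  intro <- data.frame(event = seq_len(ne), ord = 0L,
                      prefix = sim_intro_templates$prefix[it],
                      suffix = sim_intro_templates$suffix[it],
                      iri = sim_intro_templates$concept[it],
                      surface = sim_intro_templates$surface[it],
                      negated = FALSE, stringsAsFactors = FALSE)

  # theme mentions
  chunks <- list(intro)
  for (th in themes) {
    k <- stats::rpois(ne, lambda[ev_patient, th])
    tot <- sum(k)
    if (!tot) next
    ev <- rep(seq_len(ne), times = k)
    iri <- members[[th]][sample.int(length(members[[th]]), tot, replace = TRUE)]
    has_alt <- iri %in% names(alt_of)
    use_alt <- stats::runif(tot) < config$abbrev_prob & has_alt
    surface <- vapply(seq_len(tot), function(i) {
      if (use_alt[i]) { a <- alt_of[[iri[i]]]; a[[sample.int(length(a), 1L)]] }
      else pref_of[[iri[i]]][[1L]]
    }, "")
    negated <- stats::runif(tot) < config$negation_rate
    chunks[[length(chunks) + 1L]] <-
      data.frame(event = ev, ord = seq_len(tot), prefix = NA_character_,
                 suffix = NA_character_, iri = iri, surface = surface,
                 negated = negated, stringsAsFactors = FALSE)
  }
  men <- do.call(rbind, chunks)
  # assign sentence templates to non-role mentions
  need_tpl <- is.na(men$prefix)
  pos_i <- sample.int(nrow(sim_mention_templates), sum(need_tpl & !men$negated), replace = TRUE)
  men$prefix[need_tpl & !men$negated] <- sim_mention_templates$prefix[pos_i]
  men$suffix[need_tpl & !men$negated] <- sim_mention_templates$suffix[pos_i]
  neg_i <- sample.int(nrow(sim_negation_templates), sum(need_tpl & men$negated), replace = TRUE)
  men$prefix[need_tpl & men$negated] <- sim_negation_templates$prefix[neg_i]
  men$suffix[need_tpl & men$negated] <- sim_negation_templates$suffix[neg_i]

  # misspelling: single-character edits on planted (non-role) mention surfaces
  men$corrupted <- FALSE
  cand <- which(need_tpl & stats::runif(nrow(men)) < config$misspell_rate)
  if (length(cand)) {
    at <- vapply(men$surface[cand], function(s) {
      letters_at <- which(strsplit(s, "")[[1]] %in% c(letters, LETTERS))
      letters_at[sample.int(length(letters_at), 1L)]
    }, 0L)
    repl <- sample(letters, length(cand), replace = TRUE)
    same <- tolower(substring(men$surface[cand], at, at)) == repl
    repl[same] <- letters[(match(repl[same], letters) %% 26L) + 1L]
    men$surface[cand] <- mapply(corrupt_surface, men$surface[cand], at, repl,
                                USE.NAMES = FALSE)
    men$corrupted[cand] <- TRUE
  }

  # assemble documents: sentences joined by newline, offsets tracked
  men <- men[order(men$event, men$ord), , drop = FALSE]
  men$sentence <- paste0(men$prefix, men$surface, men$suffix)
  men$sent_len <- nchar(men$sentence, type = "chars")
  men$sent_start <- stats::ave(men$sent_len + 1L, men$event,
                               FUN = function(x) cumsum(c(0L, x[-length(x)])))
  men$start <- men$sent_start + nchar(men$prefix, type = "chars")
  men$end <- men$start + nchar(men$surface, type = "chars")

  text <- vapply(split(men$sentence, men$event), paste, "", collapse = "\n")
  docs <- data.frame(doc_id = doc_id, patient_id = patients$patient_id[ev_patient],
                     date = as.character(patients$inclusion_date[ev_patient] + ev_seq * 7L),
                     text = unname(text), stringsAsFactors = FALSE)
  gold <- data.frame(doc_id = doc_id[men$event], start = men$start, end = men$end,
                     surface = men$surface, iri = men$iri, negated = men$negated,
                     corrupted = men$corrupted, stringsAsFactors = FALSE)
  rownames(gold) <- NULL

  truth <- list(z_motor = stats::setNames(z, patients$patient_id),
                lambda = lambda,
                beta = config$motor_exhaustion_beta,
                expected_counts = lambda * patients$n_events,
                corrupted = gold[gold$corrupted, , drop = FALSE])
  structure(list(patients = patients, docs = docs, gold = gold,
                 truth = truth, config = config),
            class = "gold_bundle")
}

draw_patients <- function(np, config) {
  if (np == 0L) {
    return(data.frame(patient_id = character(), sex = character(),
                      age_at_diagnosis = numeric(), inclusion_age = numeric(),
                      form = character(), follow_up_days = numeric(),
                      n_events = integer(), social_status = character(),
                      lifestyle = character(), inclusion_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  sex <- ifelse(stats::runif(np) < 0.52, "M", "F")
  mu_age <- ifelse(sex == "M", 63.4, 67.15)
  sd_age <- ifelse(sex == "M", 11.88, 11.77)
  age <- pmin(pmax(stats::rnorm(np, mu_age, sd_age), 20), 90)
  incl <- age + stats::runif(np, 0, 1.5)
  form <- ifelse(stats::runif(np) < ifelse(sex == "M", 0.71, 0.60), "spinal", "bulbar")
  fu_sig <- sqrt(log(1 + (436.6 / 550.3)^2))
  follow <- round(stats::rlnorm(np, log(550.3) - fu_sig^2 / 2, fu_sig))
  ev_sig <- sqrt(log(1 + (config$events_sd / config$events_mean)^2))
  n_events <- pmax(1L, as.integer(round(stats::rlnorm(
    np, log(config$events_mean) - ev_sig^2 / 2, ev_sig))))
  social <- sample(c("single", "married", "divorced", "widower"), np, replace = TRUE,
                   prob = c(0.14, 0.64, 0.13, 0.08) / 0.99)
  lifestyle <- sample(c("alone", "family", "institution"), np, replace = TRUE,
                      prob = c(0.20, 0.78, 0.02))
  data.frame(patient_id = sprintf("P%04d", seq_len(np)), sex = sex,
             age_at_diagnosis = round(age, 1), inclusion_age = round(incl, 1),
             form = form, follow_up_days = follow, n_events = n_events,
             social_status = social, lifestyle = lifestyle,
             inclusion_date = as.Date("2013-01-02") + round(stats::runif(np, 0, 1400)),
             stringsAsFactors = FALSE)
}

#' @export
print.gold_bundle <- function(x, ...) {
  cat("<synthetic cohort bundle>\n")
  cat("  patients: ", nrow(x$patients),
      "  documents: ", nrow(x$docs),
      "  gold annotations: ", nrow(x$gold), "\n", sep = "")
  cat("  misspelled mentions: ", sum(x$gold$corrupted),
      "  negated mentions: ", sum(x$gold$negated), "\n", sep = "")
  invisible(x)
}

#' Write a bundle to disk
#'
#' Corpus directory with one `.txt` per document plus `corpus.csv`, the
#' patient table CSV, the gold standoff TSV (with the `corrupted` column)
#' and the truth record as JSON.
#'
#' @param bundle a `gold_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gold_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(bundle$docs, file.path(dir, "corpus"))
  utils::write.csv(bundle$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  gold <- bundle$gold
  utils::write.table(gold, file.path(dir, "gold.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  truth <- bundle$truth
  truth$lambda <- as.data.frame(truth$lambda)
  truth$expected_counts <- as.data.frame(truth$expected_counts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
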