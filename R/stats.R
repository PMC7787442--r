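# Population descriptions and association scans on (patient table, count
# matrix): descriptive summaries, presence/absence tables, OLS scans with
# Benjamini-Hochberg FDR and LogWorth ranking, group contrasts, correlations.

patient_numeric_fields <- c("age_at_diagnosis", "inclusion_age", "follow_up_days", "n_events")
patient_factor_fields  <- c("form", "social_status", "lifestyle")

#' Describe a patient cohort
#'
#' Per-sex and total summaries in the layout of a sociodemographic table:
#' mean, SD and min-max for the numeric fields, n (%) for the categorical
#' ones. SD of a single observation is reported as 0 (a convention; the
#' sample SD is undefined at n = 1). Missing values are dropped per field.
#'
#' @param patients patient table with columns `patient_id`, `sex` (`"F"`/`"M"`)
#'   and any of `age_at_diagnosis`, `inclusion_age`, `follow_up_days`,
#'   `n_events`, `form`, `social_status`, `lifestyle`.
#' @return list with data frames `numeric` (field, group, mean, sd, min, max)
#'   and `categorical` (field, level, group, n, pct).
#' @export
describe_population <- function(patients) {
  stopifnot("sex" %in% names(patients))
  groups <- list(F = patients[patients$sex == "F", , drop = FALSE],
                 M = patients[patients$sex == "M", , drop = FALSE],
                 total = patients)
  num <- list()
  for (f in intersect(patient_numeric_fields, names(patients))) {
    for (gn in names(groups)) {
      x <- groups[[gn]][[f]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      s <- if (length(x) > 1L) stats::sd(x) else 0
      num[[length(num) + 1L]] <- data.frame(field = f, group = gn,
                                            n = length(x), mean = mean(x), sd = s,
                                            min = min(x), max = max(x),
                                            stringsAsFactors = FALSE)
    }
  }
  cat_ <- list()
  for (f in intersect(patient_factor_fields, names(patients))) {
    for (gn in names(groups)) {
      x <- groups[[gn]][[f]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      tab <- table(x)
      cat_[[length(cat_) + 1L]] <- data.frame(field = f, level = names(tab), group = gn,
                                              n = as.integer(tab),
                                              pct = 100 * as.integer(tab) / length(x),
                                              stringsAsFactors = FALSE)
    }
  }
  list(numeric = do.call(rbind, c(num, list(data.frame()))),
       categorical = do.call(rbind, c(cat_, list(data.frame()))))
}

#' Per-concept summary of a count matrix
#'
#' For each column: mean and SD of the counts over the cohort and the
#' presence n (%) after dichotomization at the given threshold, in the
#' layout of a fully-defined-concept annotation table.
#'
#' @param matrix count matrix from [aggregate_counts()].
#' @param patients optional patient table fixing the cohort (rows are
#'   subset/ordered to `patient_id`); defaults to all matrix rows.
#' @param threshold presence threshold, default 1.
#' @return data frame: `iri`, `mean`, `sd`, `present_n`, `present_pct`,
#'   `absent_n`, `absent_pct`.
#' @export
presence_table <- function(matrix, patients = NULL, threshold = 1L) {
  if (!is.null(patients)) {
    missing <- setdiff(patients$patient_id, rownames(matrix))
    if (length(missing)) stop("patients absent from matrix: ",
                              paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    matrix <- matrix[as.character(patients$patient_id), , drop = FALSE]
  }
  bin <- dichotomize(matrix, threshold)
  n <- nrow(matrix)
  data.frame(
    iri = colnames(matrix),
    mean = colMeans(matrix),
    sd = apply(matrix, 2, function(x) if (length(x) > 1L) stats::sd(x) else 0),
    present_n = colSums(bin),
    present_pct = 100 * colSums(bin) / n,
    absent_n = n - colSums(bin),
    absent_pct = 100 * (n - colSums(bin)) / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' LogWorth of a p-value
#'
#' `-log10(p)`; the ranking statistic used for predictor importance after
#' FDR adjustment.
#'
#' @param p p-values in (0, 1].
#' @return numeric vector.
#' @export
logworth <- function(p) -log10(p)

#' Association scan of count outcomes on patient covariates
#'
#' For each outcome column of the count matrix, fits an ordinary
#' least-squares regression of the counts on the predictor set (one
#' multi-predictor model per outcome by default, or single-predictor models
#' with `joint = FALSE`). Each predictor's p-value is the marginal F-test
#' from `drop1`, which handles numeric covariates and multi-level factors
#' uniformly. Within each outcome's scan the family of predictor p-values
#' is adjusted by the Benjamini-Hochberg step-up procedure and the FDR
#' LogWorth `-log10(adjusted p)` is reported; predictors are ordered by
#' LogWorth, descending. Complete cases only (missing covariate values are
#' dropped per scan). A constant outcome is flagged and gets no p-values.
#'
#' @param matrix count matrix (rows = patients).
#' @param patients patient table with `patient_id` and the predictor columns.
#' @param outcomes character vector of matrix column names to scan.
#' @param predictors character vector of patient-table column names. Clinical
#'   state predictors (e.g. motor or cognitive state) are supplied as columns
#'   of `patients`, typically the patient's own defined-concept counts joined
#'   in beforehand.
#' @param joint fit one model with all predictors (default) or one model per
#'   predictor.
#' @return list of class `scan_result` keyed by outcome, each a data frame
#'   `predictor`, `estimate`, `p`, `p_fdr`, `logworth` (ordered by
#'   `logworth` descending), with attribute `constant` when the outcome did
#'   not vary.
#' @export
association_scan <- function(matrix, patients, outcomes, predictors,
                             joint = TRUE) {
  stopifnot(all(outcomes %in% colnames(matrix)),
            all(predictors %in% names(patients)))
  dat0 <- patients
  dat0 <- dat0[dat0$patient_id %in% rownames(matrix), , drop = FALSE]
  res <- list()
  for (oc in outcomes) {
    dat <- dat0
    dat$.y <- matrix[as.character(dat$patient_id), oc]
    dat <- dat[stats::complete.cases(dat[c(".y", predictors)]), , drop = FALSE]
    if (nrow(dat) < length(predictors) + 2L || stats::var(dat$.y) == 0) {
      out <- data.frame(predictor = predictors, estimate = NA_real_, p = NA_real_,
                        p_fdr = NA_real_, logworth = NA_real_, stringsAsFactors = FALSE)
      attr(out, "constant") <- TRUE
      res[[oc]] <- out
      next
    }
    term_stats <- function(preds_in_model) {
      fml <- stats::reformulate(preds_in_model, response = ".y")
      fit <- stats::lm(fml, data = dat)
      dr <- stats::drop1(fit, test = "F")
      co <- stats::coef(fit)
      vapply(preds_in_model, function(pr) {
        est <- if (pr %in% names(co)) co[[pr]] else NA_real_  # factors: no single slope
        c(est = est, p = dr[pr, "Pr(>F)"])
      }, c(est = 0, p = 0))
    }
    st <- if (joint) term_stats(predictors)
          else do.call(cbind, lapply(predictors, term_stats))
    p <- st["p", ]
    p_fdr <- stats::p.adjust(p, method = "BH")
    out <- data.frame(predictor = predictors, estimate = st["est", ],
                      p = p, p_fdr = p_fdr, logworth = logworth(p_fdr),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$logworth, out$p), , drop = FALSE]
    rownames(out) <- NULL
    res[[oc]] <- out
  }
  structure(res, class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  for (oc in names(x)) {
    cat("outcome:", oc, "\n")
    if (isTRUE(attr(x[[oc]], "constant"))) cat("  (constant outcome; no model fitted)\n")
    else print(format(x[[oc]], digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Two-group contrast of a count outcome
#'
#' Welch t-test between two levels of a patient-table factor, with the
#' per-group means (for a single-factor design these are the least-squares
#' means), their difference, t and p.
#'
#' @param matrix count matrix.
#' @param patients patient table.
#' @param outcome matrix column name.
#' @param factor_col patient-table column holding the grouping factor.
#' @param levels the two levels to contrast; default the factor's first two.
#' @return list: `means` (named), `difference`, `t`, `df`, `p`.
#' @export
group_contrast <- function(matrix, patients, outcome, factor_col, levels = NULL) {
  stopifnot(outcome %in% colnames(matrix), factor_col %in% names(patients))
  y <- matrix[as.character(patients$patient_id), outcome]
  f <- patients[[factor_col]]
  keep <- !is.na(y) & !is.na(f)
  y <- y[keep]; f <- as.character(f[keep])
  if (is.null(levels)) levels <- utils::head(sort(unique(f)), 2L)
  stopifnot(length(levels) == 2L, all(levels %in% f))
  a <- y[f == levels[1]]; b <- y[f == levels[2]]
  tt <- stats::t.test(a, b)
  list(means = stats::setNames(c(mean(a), mean(b)), levels),
       difference = mean(a) - mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pearson correlation of two series
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
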