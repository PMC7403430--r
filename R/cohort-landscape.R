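## Cohort landscape assembly and the cohort-level statistics:
## RPKM, within-cohort Z-scores, exact binomial CI, Fisher and Wilcoxon tests,
## and assay-aware frequency tallies.

#' Reads per kilobase per million mapped reads
#'
#' `counts * 1e9 / (geneLengthBp * totalMapped)`; vectorised over `counts`.
#'
#' @param counts gene-level read count(s), non-negative.
#' @param geneLengthBp transcript length in bp (> 0).
#' @param totalMapped total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(100, 2000, 5e7)  # 1
#' @export
rpkm <- function(counts, geneLengthBp, totalMapped) {
  if (any(geneLengthBp <= 0)) stop("geneLengthBp must be positive")
  if (any(totalMapped <= 0)) stop("totalMapped must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts * 1e9 / (geneLengthBp * totalMapped)
}

#' Within-cohort Z-scores
#'
#' Standardises expression within each cohort independently (sample SD,
#' n - 1 denominator) so that multi-cohort values are comparable despite
#' batch effects. Cohorts with fewer than two non-missing values, or zero
#' SD, yield NA.
#'
#' @param values numeric vector.
#' @param cohort cohort label per value.
#' @return numeric vector of Z-scores, aligned with `values`.
#' @export
cohortZscore <- function(values, cohort) {
  stopifnot(length(values) == length(cohort))
  z <- rep(NA_real_, length(values))
  for (g in unique(cohort)) {
    idx <- which(cohort == g & !is.na(values))
    if (length(idx) < 2L) next
    s <- stats::sd(values[idx])
    if (is.na(s) || s == 0) next
    z[idx] <- (values[idx] - mean(values[idx])) / s
  }
  z
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param x successes (0..n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return a one-row data.frame: `x`, `n`, `estimate`, `level`, `lower`,
#'   `upper`, `method`.
#' @examples
#' binomialCI(7, 252)  # 2.8% of patients, 95% CI about 1.1%-5.6%
#' @export
binomialCI <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer 0 <= x <= n with n >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  data.frame(x = x, n = n, estimate = x / n, level = level,
             lower = lower, upper = upper, method = "clopper-pearson",
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Hypergeometric exact test; the two-sided P sums all tables with
#' probability no larger than the observed one.
#'
#' @param a,b,c,d cell counts of the 2x2 table, row-wise.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return the P-value.
#' @export
fisherEnrichment <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero 2x2 table")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Ranks use midranks for ties. For combined sample size up to
#' `exactLimit` the two-sided P is exact, by enumeration of all group
#' assignments of the observed ranks (valid with ties); for larger samples
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exactLimit switch to the normal approximation above this combined
#'   size (default 20).
#' @return a list: `statistic` (Mann-Whitney U of `x`) and `p.value`.
#' @examples
#' wilcoxonCompare(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
wilcoxonCompare <- function(x, y, exactLimit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= exactLimit) {
    combos <- utils::combn(m + n, m)
    Us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    mu <- m * n / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(statistic = U, p.value = min(1, p))
}

#' Assemble the per-patient alteration landscape
#'
#' Joins the cohort table with IDH hotspot calls, upstream 1p/19q and
#' hypermutation calls, the per-patient fusion summary and MGMT expression
#' into one record per patient, sorted by patient id. Missing assays become
#' NA. Within-cohort Z-scores of expression are added when expression is
#' supplied.
#'
#' @param cohortTable data.frame with `patient_id` and `cohort` columns (plus
#'   any alteration columns already present, e.g. `mgmt_methylation`).
#' @param idhCalls optional data.frame (`patient_id`, `idh_status`), see
#'   [summarizeIdhStatus()].
#' @param upstreamCalls optional data.frame from [ingestUpstreamCalls()].
#' @param fusionSummary optional result of [fusionPatientSummary()].
#' @param expression optional numeric vector of MGMT RPKM aligned with
#'   `cohortTable` rows, or a data.frame (`patient_id`, `mgmt_expression`).
#' @return a [CohortLandscape-class].
#' @export
assembleLandscape <- function(cohortTable, idhCalls = NULL,
                              upstreamCalls = NULL, fusionSummary = NULL,
                              expression = NULL) {
  if (is.character(cohortTable))
    cohortTable <- utils::read.csv(cohortTable, stringsAsFactors = FALSE)
  if (anyDuplicated(cohortTable$patient_id))
    stop("duplicate patient_id in cohort table")
  df <- as.data.frame(cohortTable, stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)

  mergeBy <- function(df, tab, cols) {
    idx <- match(df$patient_id, as.character(tab$patient_id))
    for (col in cols) df[[col]] <- tab[[col]][idx]
    df
  }
  if (!is.null(idhCalls)) df <- mergeBy(df, idhCalls, "idh_status")
  if (!is.null(upstreamCalls))
    df <- mergeBy(df, upstreamCalls,
                  intersect(c("codel_1p19q", "hypermutation"),
                            colnames(upstreamCalls)))
  if (!is.null(fusionSummary)) {
    pp <- as.data.frame(fusionSummary$perPatient)
    df <- mergeBy(df, pp, c("fusion_positive", "fusion_names", "n_fusions"))
  }
  if (!is.null(expression)) {
    if (is.data.frame(expression)) {
      df <- mergeBy(df, expression, "mgmt_expression")
    } else {
      stopifnot(length(expression) == nrow(df))
      df$mgmt_expression <- as.numeric(expression)
    }
    df$mgmt_z <- cohortZscore(df$mgmt_expression, df$cohort)
  }
  df <- df[order(df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  new("CohortLandscape", patients = S4Vectors::DataFrame(df))
}

#' Accessors for CohortLandscape
#'
#' `patients()` returns the underlying per-patient
#' [S4Vectors::DataFrame]; `patientIds()` the sorted patient identifiers.
#'
#' @param x a [CohortLandscape-class].
#' @name CohortLandscape-accessors
NULL

#' @rdname CohortLandscape-accessors
#' @export
setMethod("patients", "CohortLandscape", function(x) x@patients)
#' @rdname CohortLandscape-accessors
#' @export
setMethod("patientIds", "CohortLandscape",
          function(x) as.character(x@patients$patient_id))

#' Write a landscape as TSV
#'
#' @param landscape a [CohortLandscape-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLandscape <- function(landscape, path) {
  utils::write.table(as.data.frame(patients(landscape)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Round percentages half-up to one decimal (base round() is half-even).
percentHalfUp <- function(p) floor(p * 1000 + 0.5) / 10

#' Tally alteration frequencies with assay-specific denominators
#'
#' For each alteration column the numerator is the number of positive
#' patients and the denominator the number of patients actually assayed
#' (non-NA); never the full cohort unless all patients were assayed.
#' Percentages are rounded half-up to one decimal.
#'
#' @param landscape a [CohortLandscape-class].
#' @param alterations named list mapping a display name to
#'   `list(column =, positive =)`, where `positive` is the token counting
#'   as altered (e.g. `"yes"`, `"mutant"`, `"unmethylated"`). By default all
#'   columns holding yes/no calls are tallied.
#' @return data.frame: `alteration`, `positive`, `assayed`, `percent`
#'   (NA when nobody was assayed).
#' @export
tallyFrequencies <- function(landscape, alterations = NULL) {
  df <- as.data.frame(patients(landscape))
  if (is.null(alterations)) {
    cand <- setdiff(colnames(df), c("patient_id", "cohort", "sex",
                                    "fusion_names", "n_fusions",
                                    "mgmt_expression", "mgmt_z"))
    alterations <- list()
    for (col in cand) {
      vals <- unique(stats::na.omit(as.character(df[[col]])))
      pos <- if (col == "idh_status") "mutant"
             else if (col == "mgmt_methylation") "unmethylated"
             else "yes"
      if (all(vals %in% c("yes", "no", "mutant", "wildtype",
                          "methylated", "unmethylated")))
        alterations[[col]] <- list(column = col, positive = pos)
    }
  }
  rows <- lapply(names(alterations), function(nm) {
    spec <- alterations[[nm]]
    v <- as.character(df[[spec$column]])
    assayed <- sum(!is.na(v))
    positive <- sum(v == spec$positive, na.rm = TRUE)
    data.frame(alteration = nm, positive = positive, assayed = assayed,
               percent = if (assayed > 0) percentHalfUp(positive / assayed)
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
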