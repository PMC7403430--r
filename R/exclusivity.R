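## Bootstrap test of mutual exclusivity among alterations, with an exact
## enumeration oracle for small instances.
##
## Rationale: if alterations are mutually exclusive, their union covers more
## patients than random reassignment of the same marginal counts would; the
## coverage statistic (patients with >= 1 alteration) is therefore compared
## with its randomisation null.

#' Build an exclusivity test input
#'
#' @param nPatients total number of patients.
#' @param positives named list of integer vectors: indices (1..nPatients) of
#'   patients positive for each alteration.
#' @param assayed optional named list of index vectors: the patients actually
#'   assayed for each alteration (defaults to all patients). Positive sets
#'   must be contained in their assayed sets.
#' @return a validated list of class `ExclusivityInput`.
#' @export
exclusivityInput <- function(nPatients, positives, assayed = NULL) {
  nPatients <- as.integer(nPatients)
  stopifnot(nPatients >= 1L, is.list(positives), length(positives) >= 1L)
  if (is.null(names(positives)) || anyDuplicated(names(positives)))
    stop("positives must be a uniquely named list")
  if (is.null(assayed))
    assayed <- stats::setNames(rep(list(seq_len(nPatients)),
                                   length(positives)), names(positives))
  if (!identical(sort(names(assayed)), sort(names(positives))))
    stop("assayed must name the same alterations as positives")
  for (nm in names(positives)) {
    p <- as.integer(positives[[nm]]); a <- as.integer(assayed[[nm]])
    if (length(p) && (any(p < 1L) || any(p > nPatients)))
      stop("positive indices for ", nm, " outside 1..nPatients")
    if (any(a < 1L) || any(a > nPatients) || anyDuplicated(a))
      stop("assayed indices for ", nm, " invalid")
    if (!all(p %in% a))
      stop("positives for ", nm, " not contained in its assayed set")
    positives[[nm]] <- p; assayed[[nm]] <- a
  }
  structure(list(nPatients = nPatients, positives = positives,
                 assayed = assayed), class = "ExclusivityInput")
}

#' Coverage: patients carrying at least one alteration
#'
#' The test statistic of the exclusivity bootstrap: the size of the union of
#' the positive sets.
#'
#' @param input an [exclusivityInput()].
#' @return integer coverage.
#' @examples
#' inp <- exclusivityInput(3, list(A = c(1, 2), B = c(2, 3)))
#' coverageCount(inp)  # 3
#' @export
coverageCount <- function(input) {
  stopifnot(inherits(input, "ExclusivityInput"))
  length(unique(unlist(input$positives, use.names = FALSE)))
}

#' Accessors for ExclusivityResult
#'
#' @param x an [ExclusivityResult-class].
#' @name ExclusivityResult-accessors
NULL

#' @rdname ExclusivityResult-accessors
#' @export
setMethod("pValue", "ExclusivityResult", function(x) x@pValue)
#' @rdname ExclusivityResult-accessors
#' @export
setMethod("observedCoverage", "ExclusivityResult",
          function(x) x@observedCoverage)

#' Bootstrap test of mutual exclusivity
#'
#' Each replicate independently reassigns, for each alteration, its positive
#' count uniformly at random without replacement within that alteration's
#' assayed set (or across all patients when
#' `permuteWithinAssayed = FALSE`), and records the resulting coverage. The
#' empirical P-value is the fraction of replicates whose coverage is
#' strictly greater than the observed coverage; it can therefore be exactly
#' 0 when the observed configuration is maximally exclusive. Because the
#' coverage statistic is discrete, strictly-greater counting is
#' anti-conservative when null replicates tie with the observed coverage;
#' the result therefore also carries `pSmoothed`,
#' `(at-least-observed + 1)/(reps + 1)`, the standard add-one Monte-Carlo
#' P-value, which is valid (stochastically no smaller than uniform under
#' the null) and is the quantity to use for inference.
#'
#' @param input an [exclusivityInput()].
#' @param nReps number of randomisations (default 10000).
#' @param seed integer seed; recorded in the result.
#' @param permuteWithinAssayed permute each alteration within its own
#'   assayed set (default) or over all patients.
#' @return an [ExclusivityResult-class].
#' @examples
#' inp <- exclusivityInput(252,
#'   positives = list(fusion = 1:7, hypermutation = 8:34,
#'                    hypomethylation = 35:86),
#'   assayed = list(fusion = 1:252, hypermutation = 1:252,
#'                  hypomethylation = 1:136))
#' bootstrapExclusivity(inp, nReps = 1000, seed = 1)
#' @export
bootstrapExclusivity <- function(input, nReps = 10000L, seed = 1L,
                                 permuteWithinAssayed = TRUE) {
  stopifnot(inherits(input, "ExclusivityInput"), nReps >= 1L)
  n <- input$nPatients
  counts <- lengths(input$positives)
  pools <- if (permuteWithinAssayed) input$assayed
           else stats::setNames(rep(list(seq_len(n)), length(counts)),
                                names(counts))
  for (nm in names(counts))
    if (counts[[nm]] > length(pools[[nm]]))
      stop("positive count for ", nm, " exceeds its randomisation pool")
  observed <- coverageCount(input)
  nReps <- as.integer(nReps)
  seed <- as.integer(seed)
  set.seed(seed)
  k <- length(counts)
  cov <- integer(nReps)
  hit <- logical(n)
  for (r in seq_len(nReps)) {
    hit[] <- FALSE
    for (j in seq_len(k)) {
      cj <- counts[[j]]
      if (cj > 0L) hit[sampleFrom(pools[[j]], cj)] <- TRUE
    }
    cov[r] <- sum(hit)
  }
  nGreater <- sum(cov > observed)
  nGreaterEqual <- sum(cov >= observed)
  new("ExclusivityResult",
      observedCoverage = as.integer(observed),
      nReps = nReps, nGreater = as.integer(nGreater),
      nGreaterEqual = as.integer(nGreaterEqual),
      pValue = nGreater / nReps,
      pSmoothed = (nGreaterEqual + 1) / (nReps + 1),
      nullMean = mean(cov), nullSd = stats::sd(cov),
      nullMax = as.integer(max(cov)),
      seed = seed, permuteWithinAssayed = permuteWithinAssayed)
}

## sample() treats a length-1 numeric pool as 1:pool; avoid that trap.
sampleFrom <- function(pool, k) {
  if (k == 0L) return(pool[0])
  if (length(pool) == 1L) pool else sample(pool, k)
}

#' Exact null probability by enumeration
#'
#' Enumerates every joint reassignment (the cartesian product of all
#' count-subsets of each alteration's assayed set, all equiprobable) and
#' returns the exact probability that coverage strictly exceeds the observed
#' coverage. Serves as the independent oracle for
#' [bootstrapExclusivity()] on small instances.
#'
#' @param input an [exclusivityInput()].
#' @param maxStates refuse instances whose enumeration exceeds this many
#'   joint states (default 1e6).
#' @param permuteWithinAssayed as in [bootstrapExclusivity()].
#' @return the exact P as a numeric scalar.
#' @examples
#' inp <- exclusivityInput(3, list(A = c(1, 2), B = c(1, 2)))
#' enumerateExclusivityExact(inp)  # 2/3
#' @export
enumerateExclusivityExact <- function(input, maxStates = 1e6,
                                      permuteWithinAssayed = TRUE) {
  stopifnot(inherits(input, "ExclusivityInput"))
  n <- input$nPatients
  counts <- lengths(input$positives)
  pools <- if (permuteWithinAssayed) input$assayed
           else stats::setNames(rep(list(seq_len(n)), length(counts)),
                                names(counts))
  total <- prod(choose(lengths(pools), counts))
  if (total > maxStates)
    stop("enumeration would visit ", format(total),
         " states (> maxStates = ", format(maxStates), ")")
  observed <- coverageCount(input)
  subsets <- lapply(seq_along(counts), function(j) {
    if (counts[[j]] == 0L) return(matrix(integer(0), nrow = 0, ncol = 1))
    utils::combn(pools[[j]], counts[[j]])
  })
  nGreater <- 0L
  nStates <- 0L
  recur <- function(j, members) {
    if (j > length(subsets)) {
      nStates <<- nStates + 1L
      if (length(unique(members)) > observed) nGreater <<- nGreater + 1L
      return(invisible())
    }
    sub <- subsets[[j]]
    for (col in seq_len(ncol(sub)))
      recur(j + 1L, c(members, sub[, col]))
  }
  recur(1L, integer(0))
  nGreater / nStates
}
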