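#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges
NULL

#' TranscriptModel: exon/CDS structure of one transcript
#'
#' Holds the spliced structure of a single transcript as needed for fusion
#' breakpoint annotation: exons as genomic intervals ordered in transcription
#' order (reverse genomic order on the minus strand), plus the genomic
#' coordinates of the first and last CDS base when the transcript is coding.
#' Coordinates follow the GTF convention: 1-based, inclusive. Chromosome
#' names are stored without a "chr" prefix.
#'
#' @slot transcriptId,geneId,geneName,biotype single character strings.
#' @slot chrom chromosome name, normalised to un-prefixed (e.g. "10").
#' @slot strand "+" or "-".
#' @slot exons an [IRanges::IRanges] of exon intervals, sorted 5' to 3' in
#'   transcription order; non-overlapping.
#' @slot cdsStartGenomic,cdsEndGenomic genomic coordinate of the first/last
#'   CDS base in transcription order, or `NA_integer_` for non-coding models.
#'
#' @seealso [readGtf()], [genomicToMrna()], [distanceToStartCodon()]
#' @export
setClass("TranscriptModel",
  slots = c(
    transcriptId = "character",
    geneId = "character",
    geneName = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cdsStartGenomic = "integer",
    cdsEndGenomic = "integer",
    biotype = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msgs <- c(msgs, "transcript must have at least one exon")
  if (length(ex) > 1L) {
    st <- IRanges::start(ex)
    ord <- if (identical(object@strand, "+")) st else rev(st)
    if (is.unsorted(ord, strictly = TRUE))
      msgs <- c(msgs, "exons must be sorted in transcription order")
    red <- IRanges::reduce(ex)
    if (sum(IRanges::width(red)) != sum(IRanges::width(ex)))
      msgs <- c(msgs, "exons must be non-overlapping")
  }
  cs <- object@cdsStartGenomic
  if (!is.na(cs) && length(ex) > 0L &&
      !any(cs >= IRanges::start(ex) & cs <= IRanges::end(ex)))
    msgs <- c(msgs, "CDS start must lie within an exon")
  ce <- object@cdsEndGenomic
  if (is.na(cs) != is.na(ce))
    msgs <- c(msgs, "cdsStartGenomic and cdsEndGenomic must both be set or both NA")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TranscriptModel compact display of structure and CDS.
#' @param object a `TranscriptModel`.
#' @export
setMethod("show", "TranscriptModel", function(object) {
  cds <- if (is.na(object@cdsStartGenomic)) "non-coding"
         else sprintf("CDS %d..%d", object@cdsStartGenomic, object@cdsEndGenomic)
  cat(sprintf("TranscriptModel %s (%s, %s) %s:%s  %d exon(s), mRNA %d nt, %s\n",
              object@transcriptId, object@geneName, object@biotype,
              object@chrom, object@strand, length(object@exons),
              mrnaLength(object), cds))
})

#' ExclusivityResult: bootstrap test of mutual exclusivity
#'
#' Result container for [bootstrapExclusivity()]. The test statistic is the
#' coverage: the number of patients carrying at least one of the alterations.
#' The null randomly reassigns each alteration's positive count among its
#' assayed patients; the empirical P-value is the fraction of replicates whose
#' coverage strictly exceeds the observed coverage (so P can be exactly 0).
#' A tie-inclusive add-one P, (at-least-observed + 1)/(reps + 1), is carried
#' alongside; see [bootstrapExclusivity()] for why both are reported.
#'
#' @slot observedCoverage integer, patients with >= 1 alteration as observed.
#' @slot nReps,nGreater,nGreaterEqual integer: replicates run, replicates
#'   with null coverage strictly greater than observed, and replicates with
#'   null coverage at least the observed.
#' @slot pValue,pSmoothed numeric: `nGreater/nReps` (the strictly-greater
#'   empirical P) and `(nGreaterEqual + 1)/(nReps + 1)`, the tie-inclusive
#'   add-one Monte-Carlo P, which is never anti-conservative.
#' @slot nullMean,nullSd,nullMax summary of the null coverage distribution.
#' @slot seed integer seed used for the randomisation.
#' @slot permuteWithinAssayed logical; whether each alteration was permuted
#'   within its own assayed set (default) or across all patients.
#'
#' @seealso [bootstrapExclusivity()], [enumerateExclusivityExact()]
#' @export
setClass("ExclusivityResult",
  slots = c(
    observedCoverage = "integer",
    nReps = "integer",
    nGreater = "integer",
    nGreaterEqual = "integer",
    pValue = "numeric",
    pSmoothed = "numeric",
    nullMean = "numeric",
    nullSd = "numeric",
    nullMax = "integer",
    seed = "integer",
    permuteWithinAssayed = "logical"
  )
)

setValidity("ExclusivityResult", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (object@nGreater > object@nReps)
    msgs <- c(msgs, "nGreater cannot exceed nReps")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ExclusivityResult display observed coverage, null summary and P.
#' @param object an `ExclusivityResult`.
#' @export
setMethod("show", "ExclusivityResult", function(object) {
  cat(sprintf("ExclusivityResult: observed coverage %d patients\n",
              object@observedCoverage))
  cat(sprintf("  null coverage over %d replicates: mean %.2f, sd %.2f, max %d\n",
              object@nReps, object@nullMean, object@nullSd, object@nullMax))
  cat(sprintf("  P (strictly greater rule) = %s;  P smoothed = %.4g  [seed %d]\n",
              format(object@pValue), object@pSmoothed, object@seed))
})

#' CohortLandscape: per-patient alteration and expression matrix
#'
#' One row per patient (sorted by patient id), holding cohort membership, sex,
#' alteration calls (character "yes"/"no"/NA, plus IDH/1p19q status tokens),
#' MGMT expression (RPKM) and its within-cohort Z-score where computed.
#' Patient ids are unique by construction.
#'
#' @slot patients a [S4Vectors::DataFrame] with at least a `patient_id`
#'   column; one row per patient.
#'
#' @seealso [assembleLandscape()], [tallyFrequencies()]
#' @export
setClass("CohortLandscape", slots = c(patients = "DataFrame"))

setValidity("CohortLandscape", function(object) {
  df <- object@patients
  if (!"patient_id" %in% colnames(df))
    return("patients must have a 'patient_id' column")
  if (anyDuplicated(df$patient_id))
    return("duplicate patient_id")
  if (is.unsorted(as.character(df$patient_id)))
    return("patients must be sorted by patient_id")
  TRUE
})

#' @describeIn CohortLandscape display dimensions and column names.
#' @param object a `CohortLandscape`.
#' @export
setMethod("show", "CohortLandscape", function(object) {
  df <- object@patients
  cat(sprintf("CohortLandscape: %d patients, %d columns\n", nrow(df), ncol(df)))
  cat("  columns:", paste(colnames(df), collapse = ", "), "\n")
  if ("cohort" %in% colnames(df)) {
    tab <- table(df$cohort)
    cat("  cohorts:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})
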