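## Fusion-candidate ingestion, blacklist filtering and structural annotation.

FUSION_TSV_COLUMNS <- c("FusionName", "LeftGene", "LeftBreakpoint",
                        "RightGene", "RightBreakpoint",
                        "JunctionReadCount", "SpanningFragCount", "SampleID")

#' Path to a packaged resource table
#'
#' @param name file name under the package's `extdata` directory.
#' @return absolute path to the resource.
#' @export
fusionscapeResource <- function(name) {
  p <- system.file("extdata", name, package = "fusionscape", mustWork = TRUE)
  p
}

#' Parse "chrom:pos:strand" breakpoint strings
#'
#' @param x character vector like `"10:131265000:+"` (a "chr" prefix on the
#'   chromosome is accepted and stripped).
#' @return a data.frame with columns `chrom`, `pos`, `strand`.
#' @export
parseBreakpoint <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("unparsable breakpoint '", x[bad[1L]], "' (row ", bad[1L],
         "): expected chrom:pos:strand")
  m <- do.call(rbind, parts)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos) || any(pos <= 0L)) {
    bad <- which(is.na(pos) | pos <= 0L)[1L]
    stop("unparsable breakpoint position in '", x[bad], "' (row ", bad, ")")
  }
  if (!all(m[, 3L] %in% c("+", "-")))
    stop("breakpoint strand must be '+' or '-'")
  data.frame(chrom = normalizeChrom(m[, 1L]), pos = pos, strand = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Read a fusion-candidate table
#'
#' Reads the tab-separated candidate dialect emitted by split-read fusion
#' callers: one row per candidate junction with left/right partner genes,
#' `chrom:pos:strand` breakpoints, junction-read and spanning-fragment
#' support, and the sample identifier.
#'
#' @param path path to a TSV with header columns `FusionName`, `LeftGene`,
#'   `LeftBreakpoint`, `RightGene`, `RightBreakpoint`, `JunctionReadCount`,
#'   `SpanningFragCount`, `SampleID`.
#' @return a data.frame with one row per candidate and parsed breakpoint
#'   columns `left_chrom`/`left_pos`/`left_strand` (and right-side
#'   counterparts).
#' @export
readFusionCandidates <- function(path) {
  if (!file.exists(path)) stop("fusion candidate file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(FUSION_TSV_COLUMNS, colnames(tab))
  if (length(missing))
    stop("fusion table lacks required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    fusion_name = tab$FusionName,
    left_gene = tab$LeftGene,
    right_gene = tab$RightGene,
    junction_reads = as.integer(tab$JunctionReadCount),
    spanning_frags = as.integer(tab$SpanningFragCount),
    sample_id = tab$SampleID,
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(!nzchar(out$left_gene)) || any(!nzchar(out$right_gene)))
      stop("empty gene name in fusion table")
    lb <- parseBreakpoint(tab$LeftBreakpoint)
    rb <- parseBreakpoint(tab$RightBreakpoint)
    out$left_chrom <- lb$chrom; out$left_pos <- lb$pos; out$left_strand <- lb$strand
    out$right_chrom <- rb$chrom; out$right_pos <- rb$pos; out$right_strand <- rb$strand
  } else {
    out[c("left_chrom", "right_chrom", "left_strand", "right_strand")] <- character(0)
    out[c("left_pos", "right_pos")] <- integer(0)
  }
  out
}

#' Write a fusion-candidate table in the caller dialect
#'
#' Inverse of [readFusionCandidates()]; used by the synthetic generators.
#' @param candidates a candidate data.frame as returned by
#'   [readFusionCandidates()] or [genFusionCandidates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFusionCandidates <- function(candidates, path) {
  tab <- data.frame(
    FusionName = candidates$fusion_name,
    LeftGene = candidates$left_gene,
    LeftBreakpoint = sprintf("%s:%d:%s", candidates$left_chrom,
                             candidates$left_pos, candidates$left_strand),
    RightGene = candidates$right_gene,
    RightBreakpoint = sprintf("%s:%d:%s", candidates$right_chrom,
                              candidates$right_pos, candidates$right_strand),
    JunctionReadCount = candidates$junction_reads,
    SpanningFragCount = candidates$spanning_frags,
    SampleID = candidates$sample_id,
    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readPairResource <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Default regular expressions matching uncharacterised gene names
#'
#' Clone-derived and positional gene symbols (LOC, orf, genomic-clone and
#' antisense identifiers) that indicate an uncharacterised locus.
#' @return character vector of regular expressions.
#' @export
uncharacterizedGenePatterns <- function() {
  c("^LOC\\d+", "^C\\d+orf\\d+", "^A[CLP]\\d{6}", "-AS\\d$", "^LINC\\d+")
}

#' Filter fusion candidates by the four removal rules
#'
#' Removes, in fixed precedence, candidates (1) present in normal tissues,
#' (2) involving mitochondrial genes, (3) involving uncharacterised genes and
#' (4) joining two paralogs. Precedence makes the audit deterministic when a
#' row matches several rules. Filtering is monotone and idempotent.
#'
#' @param candidates data.frame from [readFusionCandidates()] (or the
#'   synthetic generator).
#' @param normalBlacklist data.frame or TSV path with columns
#'   `gene1`,`gene2`: gene pairs fused in normal tissue (unordered match).
#' @param paralogPairs data.frame or TSV path with columns `gene1`,`gene2`:
#'   unordered paralog pairs.
#' @param uncharacterizedPatterns character vector of regexes; a candidate is
#'   removed if either partner matches any.
#' @param mitoPrefixes character vector of gene-name prefixes marking
#'   mitochondrial genes.
#' @return a list with `retained` (data.frame of surviving candidates) and
#'   `audit` (a [S4Vectors::DataFrame] with one removal reason per input row,
#'   `"retained"` for survivors).
#' @examples
#' models <- genGeneModels(seed = 1)
#' cand <- genFusionCandidates(models, nTrue = 1, seed = 1)
#' res <- filterCandidates(cand)
#' table(res$audit$reason)
#' @export
filterCandidates <- function(candidates,
                             normalBlacklist = fusionscapeResource("normal_tissue_fusions.tsv"),
                             paralogPairs = fusionscapeResource("paralog_pairs.tsv"),
                             uncharacterizedPatterns = uncharacterizedGenePatterns(),
                             mitoPrefixes = "MT-") {
  nb <- readPairResource(normalBlacklist)
  pp <- readPairResource(paralogPairs)
  n <- nrow(candidates)
  reason <- rep("retained", n)
  if (n > 0L) {
    key <- pairKey(candidates$left_gene, candidates$right_gene)
    inNormal <- key %in% pairKey(nb$gene1, nb$gene2)
    mitoHit <- function(g) Reduce(`|`, lapply(mitoPrefixes, startsWith, x = g),
                                  accumulate = FALSE)
    isMito <- mitoHit(candidates$left_gene) | mitoHit(candidates$right_gene)
    unchHit <- function(g) Reduce(`|`, lapply(uncharacterizedPatterns, grepl, x = g))
    isUnch <- unchHit(candidates$left_gene) | unchHit(candidates$right_gene)
    isParalog <- key %in% pairKey(pp$gene1, pp$gene2)
    reason[isParalog] <- "paralog"
    reason[isUnch] <- "uncharacterized"
    reason[isMito] <- "mitochondrial"
    reason[inNormal] <- "normal_tissue"
  }
  audit <- S4Vectors::DataFrame(
    fusion_name = if (n) candidates$fusion_name else character(0),
    left_gene = if (n) candidates$left_gene else character(0),
    right_gene = if (n) candidates$right_gene else character(0),
    reason = reason)
  list(retained = candidates[reason == "retained", , drop = FALSE],
       audit = audit)
}

#' FusionAnnotation: structural classification of one fusion junction
#'
#' Produced by [annotateFusion()]. The category is one of
#' `five_prime_utr_swap` (the 5' partner contributes only untranslated
#' sequence and the acceptor gene's CDS is intact: a promoter swap),
#' `chimeric_in_frame`, `chimeric_out_of_frame`, or `unresolved` (a
#' breakpoint off an exon boundary or outside the models).
#'
#' @slot fusionName,sampleId identifiers of the annotated candidate.
#' @slot category character, see above.
#' @slot partnerCdsNt integer nt of 5'-partner CDS retained (0 for UTR swap).
#' @slot rightOffsetToStartCodon signed integer nt from the acceptor-side
#'   breakpoint to the acceptor ATG (positive = upstream).
#' @slot rightCdsIntact logical: breakpoint at or upstream of the acceptor ATG.
#' @slot domainsRetained named logical: acceptor protein domains fully
#'   preserved in the fused product.
#' @slot breakpointOnExonBoundary named logical of length 2 (`left`, `right`).
#' @slot diagnostic character; non-empty only for `unresolved`.
#' @export
setClass("FusionAnnotation",
  slots = c(
    fusionName = "character", sampleId = "character",
    category = "character",
    partnerCdsNt = "integer",
    rightOffsetToStartCodon = "integer",
    rightCdsIntact = "logical",
    domainsRetained = "logical",
    breakpointOnExonBoundary = "logical",
    diagnostic = "character"))

setValidity("FusionAnnotation", function(object) {
  ok <- c("five_prime_utr_swap", "chimeric_in_frame",
          "chimeric_out_of_frame", "unresolved")
  msgs <- character()
  if (!object@category %in% ok)
    msgs <- c(msgs, "unknown category")
  if (identical(object@category, "five_prime_utr_swap") &&
      (object@partnerCdsNt != 0L || !isTRUE(object@rightCdsIntact)))
    msgs <- c(msgs, "five_prime_utr_swap requires partnerCdsNt == 0 and intact acceptor CDS")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FusionAnnotation one-line structural summary.
#' @param object a `FusionAnnotation`.
#' @export
setMethod("show", "FusionAnnotation", function(object) {
  cat(sprintf("FusionAnnotation %s [%s]: %s\n", object@fusionName,
              object@sampleId, object@category))
  cat(sprintf("  partner CDS retained: %d nt; acceptor breakpoint to ATG: %+d nt; acceptor CDS intact: %s\n",
              object@partnerCdsNt, object@rightOffsetToStartCodon,
              object@rightCdsIntact))
  if (length(object@domainsRetained))
    cat("  domains retained:",
        paste(sprintf("%s=%s", names(object@domainsRetained),
                      object@domainsRetained), collapse = ", "), "\n")
  if (nzchar(object@diagnostic)) cat("  note:", object@diagnostic, "\n")
})

#' Annotate a fusion candidate against its partner gene models
#'
#' Reconstructs the chimeric transcript structure at the junction. The donor
#' (left) breakpoint must be the last base of a left-model exon and the
#' acceptor (right) breakpoint the first base of a right-model exon in
#' transcription order; otherwise the candidate is classed `unresolved` with
#' a diagnostic (never an exception). For resolvable junctions:
#' `partnerCdsNt` is the spliced CDS length the 5' partner contributes;
#' the fusion is a 5'UTR swap when that is zero and the acceptor CDS is
#' intact, otherwise chimeric, in frame when the contributed coding length
#' plus the acceptor-side distance to the ATG is divisible by 3. A domain of
#' the acceptor protein is retained when its full amino-acid range lies in
#' the translated product.
#'
#' @param candidate one row of a candidate data.frame
#'   (see [readFusionCandidates()]).
#' @param leftModel,rightModel [TranscriptModel-class] objects for the donor
#'   and acceptor genes.
#' @param domains optional data.frame (`domain`,`aa_start`,`aa_end`) of
#'   acceptor protein domains, e.g. from
#'   `fusionscapeResource("mgmt_domains.tsv")`.
#' @return a [FusionAnnotation-class].
#' @export
annotateFusion <- function(candidate, leftModel, rightModel, domains = NULL) {
  name <- as.character(candidate$fusion_name)
  sid <- as.character(candidate$sample_id)
  dom <- if (is.null(domains)) data.frame(domain = character(0),
                                          aa_start = integer(0),
                                          aa_end = integer(0))
         else readPairResource(domains)
  noDomains <- stats::setNames(logical(nrow(dom)), dom$domain)

  unresolved <- function(msg, leftOK = FALSE, rightOK = FALSE) {
    new("FusionAnnotation", fusionName = name, sampleId = sid,
        category = "unresolved", partnerCdsNt = NA_integer_,
        rightOffsetToStartCodon = NA_integer_, rightCdsIntact = NA,
        domainsRetained = noDomains,
        breakpointOnExonBoundary = c(left = leftOK, right = rightOK),
        diagnostic = msg)
  }

  lClass <- exonBoundaryClass(leftModel, candidate$left_pos)
  rClass <- exonBoundaryClass(rightModel, candidate$right_pos)
  leftOK <- identical(lClass, "donor_boundary")
  rightOK <- identical(rClass, "acceptor_boundary")
  if (lClass == "not_exonic" || rClass == "not_exonic")
    return(unresolved("breakpoint outside exons of the supplied models",
                      leftOK, rightOK))
  if (!leftOK || !rightOK)
    return(unresolved(sprintf(
      "breakpoint not on the expected exon boundary (left: %s, right: %s)",
      lClass, rClass), leftOK, rightOK))
  if (!isCoding(rightModel))
    return(unresolved("acceptor transcript is non-coding", leftOK, rightOK))

  bpOffset <- genomicToMrna(leftModel, candidate$left_pos)
  partnerCdsNt <- 0L
  if (isCoding(leftModel)) {
    atg <- genomicToMrna(leftModel, cdsStartGenomic(leftModel))
    if (bpOffset >= atg) partnerCdsNt <- bpOffset - atg + 1L
  }
  rightOffset <- distanceToStartCodon(rightModel, candidate$right_pos)
  rightCdsIntact <- rightOffset >= 0L

  if (partnerCdsNt == 0L && rightCdsIntact) {
    category <- "five_prime_utr_swap"
  } else {
    inFrame <- (partnerCdsNt + rightOffset) %% 3L == 0L
    category <- if (inFrame) "chimeric_in_frame" else "chimeric_out_of_frame"
  }

  ## acceptor CDS nt lost 5' of the junction (0 when the CDS is intact)
  lostNt <- max(0L, -rightOffset)
  translated <- category %in% c("five_prime_utr_swap", "chimeric_in_frame")
  domOK <- if (nrow(dom) == 0L) noDomains else
    stats::setNames(translated & (dom$aa_start - 1L) * 3L >= lostNt, dom$domain)

  new("FusionAnnotation", fusionName = name, sampleId = sid,
      category = category, partnerCdsNt = partnerCdsNt,
      rightOffsetToStartCodon = as.integer(rightOffset),
      rightCdsIntact = rightCdsIntact, domainsRetained = domOK,
      breakpointOnExonBoundary = c(left = TRUE, right = TRUE),
      diagnostic = "")
}

#' Summarise fusion calls per patient
#'
#' Counts distinct fusion events and fusion-positive patients; a patient
#' carrying two fusions counts once in the patient tally. Sample ids that do
#' not resolve to a cohort patient are skipped with a warning.
#'
#' @param events data.frame with columns `fusion_name` and `sample_id`
#'   (retained candidates, or annotations flattened to a table).
#' @param cohortTable data.frame with a `patient_id` column.
#' @return a list: `nFusions` (distinct fusion names), `nPatients`
#'   (fusion-positive patients), and `perPatient`, a
#'   [S4Vectors::DataFrame] keyed by patient id with `fusion_positive`
#'   ("yes"/"no"), a comma-separated `fusion_names` column and `n_fusions`.
#' @export
fusionPatientSummary <- function(events, cohortTable) {
  ids <- as.character(cohortTable$patient_id)
  if (nrow(events)) {
    known <- events$sample_id %in% ids
    if (any(!known)) {
      warning("skipping ", sum(!known), " fusion event(s) with unknown sample id: ",
              paste(unique(events$sample_id[!known]), collapse = ", "))
      events <- events[known, , drop = FALSE]
    }
  }
  byPatient <- split(events$fusion_name, factor(events$sample_id, levels = ids))
  nFus <- lengths(byPatient)
  perPatient <- S4Vectors::DataFrame(
    patient_id = ids,
    fusion_positive = ifelse(nFus > 0L, "yes", "no"),
    fusion_names = vapply(byPatient, function(x)
      paste(unique(x), collapse = ","), character(1)),
    n_fusions = as.integer(nFus))
  list(nFusions = length(unique(events$fusion_name)),
       nPatients = sum(nFus > 0L),
       perPatient = perPatient)
}
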