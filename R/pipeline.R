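## End-to-end orchestration: ingest -> screen -> annotate -> call -> assemble
## -> tally/CI -> exclusivity, from a single configuration, with a
## machine-readable report.

defaultAlterationMap <- function() {
  list(hypomethylation = list(column = "hypomethylation", positive = "yes"),
       hypermutation = list(column = "hypermutation", positive = "yes"),
       fusion = list(column = "fusion_positive", positive = "yes"))
}

#' Default pipeline configuration
#'
#' @param inputs named list of input paths (`cohort_csv`, `fusion_tsv`,
#'   `gtf`, `pileup_tsv`, `upstream_csv`).
#' @param outdir output directory.
#' @param seed integer master seed (stage seeds are derived from it).
#' @return a config list accepted by [runPipeline()].
#' @export
pipelineConfig <- function(inputs, outdir, seed = 1L) {
  list(inputs = inputs, outdir = outdir, seed = as.integer(seed),
       thresholds = list(min_depth = 5L, min_alt_reads = 2L, min_vaf = 0.1,
                         ci_level = 0.95, n_reps = 10000L),
       resources = list(
         blacklist = fusionscapeResource("normal_tissue_fusions.tsv"),
         paralogs = fusionscapeResource("paralog_pairs.tsv"),
         domains = fusionscapeResource("mgmt_domains.tsv")),
       alterations = defaultAlterationMap())
}

stageStop <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the analysis pipeline end to end
#'
#' Executes ingest, fusion screening, structural annotation, hotspot
#' calling, landscape assembly, frequency tallies with an exact binomial CI
#' for the fusion frequency, and the exclusivity bootstrap, in that order.
#' Progress goes to standard error; structured results are written as
#' `report.json`, `landscape.tsv` and `audit.tsv` under the configured
#' output directory. Deterministic given the configuration and seed.
#'
#' @param config a list from [pipelineConfig()], or a path to a YAML file
#'   with the same structure.
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$outdir))
  thr <- utils::modifyList(pipelineConfig(config$inputs, config$outdir)$thresholds,
                           if (is.null(config$thresholds)) list() else config$thresholds)
  res <- utils::modifyList(pipelineConfig(config$inputs, config$outdir)$resources,
                           if (is.null(config$resources)) list() else config$resources)
  alt <- if (is.null(config$alterations)) defaultAlterationMap() else config$alterations
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  progress <- function(...) message("[fusionscape] ", ...)

  need <- c("cohort_csv", "fusion_tsv", "gtf", "pileup_tsv", "upstream_csv")
  for (nm in need) {
    p <- config$inputs[[nm]]
    stage <- if (nm == "gtf") "gene_model" else "ingest"
    if (is.null(p) || !file.exists(p))
      stageStop(stage, simpleError(paste0("missing input '", nm, "'",
                                          if (!is.null(p)) paste0(": ", p))))
  }

  progress("ingest: reading inputs")
  cohort <- tryCatch(utils::read.csv(config$inputs$cohort_csv,
                                     stringsAsFactors = FALSE),
                     error = function(e) stageStop("ingest", e))
  candidates <- tryCatch(readFusionCandidates(config$inputs$fusion_tsv),
                         error = function(e) stageStop("ingest", e))
  models <- tryCatch(readGtf(config$inputs$gtf),
                     error = function(e) stageStop("gene_model", e))
  pileup <- tryCatch(readPileup(config$inputs$pileup_tsv),
                     error = function(e) stageStop("ingest", e))
  upstreamRaw <- tryCatch(utils::read.csv(config$inputs$upstream_csv,
                                          stringsAsFactors = FALSE),
                          error = function(e) stageStop("ingest", e))

  progress("screen: filtering ", nrow(candidates), " fusion candidate(s)")
  screened <- tryCatch(
    filterCandidates(candidates, normalBlacklist = res$blacklist,
                     paralogPairs = res$paralogs),
    error = function(e) stageStop("fusion_screen", e))
  retained <- screened$retained

  progress("annotate: ", nrow(retained), " retained candidate(s)")
  byGene <- tryCatch(selectRepresentativeTranscript(models),
                     error = function(e) stageStop("gene_model", e))
  annotations <- list()
  annSkipped <- 0L
  for (i in seq_len(nrow(retained))) {
    row <- retained[i, ]
    lmod <- byGene[[row$left_gene]]; rmod <- byGene[[row$right_gene]]
    if (is.null(lmod) || is.null(rmod)) {
      warning("no gene model for ", row$fusion_name, "; annotation skipped")
      annSkipped <- annSkipped + 1L
      next
    }
    annotations[[length(annotations) + 1L]] <- tryCatch(
      annotateFusion(row, lmod, rmod, domains = res$domains),
      error = function(e) stageStop("fusion_screen", e))
  }

  progress("call: hotspot status from ", nrow(pileup), " pileup site(s)")
  calls <- tryCatch(
    callHotspots(pileup, minDepth = thr$min_depth,
                 minAltReads = thr$min_alt_reads, minVaf = thr$min_vaf),
    error = function(e) stageStop("variant_status", e))
  idh <- summarizeIdhStatus(calls)
  upstream <- tryCatch(ingestUpstreamCalls(upstreamRaw, cohort$patient_id),
                       error = function(e) stageStop("variant_status", e))

  progress("assemble: landscape for ", nrow(cohort), " patient(s)")
  fusSummary <- tryCatch(fusionPatientSummary(retained, cohort),
                         error = function(e) stageStop("cohort_landscape", e))
  expr <- if ("mgmt_expression" %in% colnames(cohort)) cohort$mgmt_expression
  landscape <- tryCatch(
    assembleLandscape(cohort, idhCalls = idh, upstreamCalls = upstream,
                      fusionSummary = fusSummary, expression = expr),
    error = function(e) stageStop("cohort_landscape", e))

  freq <- tallyFrequencies(landscape)
  ci <- binomialCI(fusSummary$nPatients, nrow(cohort), thr$ci_level)

  progress("exclusivity: bootstrap with ", thr$n_reps, " replicate(s)")
  df <- as.data.frame(patients(landscape))
  positives <- list(); assayedSets <- list()
  for (nm in names(alt)) {
    col <- as.character(df[[alt[[nm]]$column]])
    positives[[nm]] <- which(!is.na(col) & col == alt[[nm]]$positive)
    assayedSets[[nm]] <- which(!is.na(col))
  }
  excl <- tryCatch({
    inp <- exclusivityInput(nrow(df), positives, assayedSets)
    bootstrapExclusivity(inp, nReps = thr$n_reps, seed = seed)
  }, error = function(e) stageStop("exclusivity", e))

  report <- list(
    software = list(package = "fusionscape",
                    version = as.character(utils::packageVersion("fusionscape"))),
    seed = seed,
    config = list(inputs = config$inputs, thresholds = thr,
                  outdir = config$outdir),
    stages = list(
      screen = list(input = nrow(candidates), retained = nrow(retained),
                    removed = as.list(table(
                      screened$audit$reason[screened$audit$reason != "retained"]))),
      annotate = list(input = nrow(retained),
                      annotated = length(annotations), skipped = annSkipped),
      hotspot = list(sites = nrow(pileup), calls = nrow(calls),
                     na_calls = sum(is.na(calls$status)))),
    fusions = list(
      n_events = nrow(retained), n_patients = fusSummary$nPatients,
      n_distinct = fusSummary$nFusions,
      categories = as.list(table(vapply(annotations, function(a) a@category,
                                        character(1)))),
      frequency_percent = percentHalfUp(ci$estimate),
      ci_level = thr$ci_level,
      ci_lower_percent = percentHalfUp(ci$lower),
      ci_upper_percent = percentHalfUp(ci$upper)),
    frequencies = freq,
    exclusivity = list(
      observed_coverage = observedCoverage(excl),
      n_reps = excl@nReps, n_greater = excl@nGreater,
      p_value = pValue(excl), p_smoothed = excl@pSmoothed,
      null_mean = excl@nullMean, null_sd = excl@nullSd,
      null_max = excl@nullMax, seed = excl@seed))

  writeLandscape(landscape, file.path(config$outdir, "landscape.tsv"))
  utils::write.table(as.data.frame(screened$audit),
                     file.path(config$outdir, "audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  progress("done: report written to ",
           file.path(config$outdir, "report.json"))
  invisible(report)
}
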