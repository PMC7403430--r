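## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth, so all stages are testable without external downloads.
## All generators are pure functions of (configuration, seed).

#' Generate a synthetic multi-cohort patient table
#'
#' Emulates a recurrent-glioma cohort with partially assayed binary
#' alterations at exact marginal counts. Positive sets are drawn first
#' (`disjoint`: pairwise disjoint; `independent`: independently;
#' `nested`: each smaller positive set inside the next larger one), then each
#' alteration's assayed set is completed around its positives uniformly at
#' random; patients outside an assayed set get NA for that alteration.
#'
#' @param nPatients cohort size.
#' @param counts named integer vector: positive patients per alteration.
#' @param assayed named integer vector: patients assayed per alteration
#'   (default: all). Each count must satisfy
#'   `count <= assayed <= nPatients`.
#' @param overlapMode `"disjoint"`, `"independent"` or `"nested"`.
#' @param cohorts named numeric vector of cohort proportions (must sum
#'   to 1); sizes are fixed by largest-remainder rounding, membership
#'   shuffled.
#' @param femaleFraction proportion of female patients (default 0.45).
#' @param seed integer seed.
#' @return a list: `table` (data.frame: `patient_id`, `cohort`, `sex`, one
#'   yes/no/NA column per alteration) and `truth` (positive and assayed index
#'   sets per alteration).
#' @examples
#' syn <- genCohort(252,
#'   counts = c(fusion = 7, hypermutation = 27, hypomethylation = 52),
#'   assayed = c(fusion = 252, hypermutation = 252, hypomethylation = 136),
#'   overlapMode = "disjoint", seed = 1)
#' colSums(syn$table[-(1:3)] == "yes", na.rm = TRUE)
#' @export
genCohort <- function(nPatients, counts, assayed = NULL,
                      overlapMode = c("disjoint", "independent", "nested"),
                      cohorts = c(CGGA = 0.42, SMC = 0.16, GLSS = 0.28,
                                  TCGA = 0.02, Other = 0.12),
                      femaleFraction = 0.45, seed = 1L) {
  overlapMode <- match.arg(overlapMode)
  nPatients <- as.integer(nPatients)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named")
  if (is.null(assayed))
    assayed <- stats::setNames(rep(nPatients, length(counts)), names(counts))
  assayed <- stats::setNames(as.integer(assayed[names(counts)]), names(counts))
  if (any(is.na(assayed))) stop("assayed must cover every alteration in counts")
  if (any(counts > assayed) || any(assayed > nPatients) || any(counts < 0))
    stop("need 0 <= count <= assayed <= nPatients for every alteration")
  if (overlapMode == "disjoint" && sum(counts) > nPatients)
    stop("disjoint mode infeasible: positive counts sum to ", sum(counts),
         " > ", nPatients, " patients")
  if (abs(sum(cohorts) - 1) > 1e-8) stop("cohort proportions must sum to 1")
  if (femaleFraction < 0 || femaleFraction > 1)
    stop("femaleFraction must lie in [0, 1]")

  set.seed(as.integer(seed))
  ids <- sprintf("P%04d", seq_len(nPatients))

  ## cohort sizes by largest remainder, then shuffled membership
  quota <- cohorts * nPatients
  sizes <- floor(quota)
  rem <- nPatients - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  cohortCol <- sample(rep(names(cohorts), times = sizes))

  sex <- rep("M", nPatients)
  nF <- round(femaleFraction * nPatients)
  if (nF > 0) sex[sampleFrom(seq_len(nPatients), nF)] <- "F"

  positives <- vector("list", length(counts))
  names(positives) <- names(counts)
  if (overlapMode == "disjoint") {
    perm <- sample(nPatients)
    at <- 0L
    for (nm in names(counts)) {
      positives[[nm]] <- sort(perm[seq_len(counts[[nm]]) + at])
      at <- at + counts[[nm]]
    }
  } else if (overlapMode == "independent") {
    for (nm in names(counts))
      positives[[nm]] <- sort(sampleFrom(seq_len(nPatients), counts[[nm]]))
  } else { # nested
    ord <- names(sort(counts, decreasing = TRUE))
    prev <- seq_len(nPatients)
    for (nm in ord) {
      positives[[nm]] <- sort(sampleFrom(prev, counts[[nm]]))
      prev <- positives[[nm]]
    }
  }

  assayedSets <- vector("list", length(counts))
  names(assayedSets) <- names(counts)
  tab <- data.frame(patient_id = ids, cohort = cohortCol, sex = sex,
                    stringsAsFactors = FALSE)
  for (nm in names(counts)) {
    pos <- positives[[nm]]
    pool <- setdiff(seq_len(nPatients), pos)
    fill <- assayed[[nm]] - length(pos)
    aset <- sort(c(pos, if (fill > 0) sampleFrom(pool, fill)))
    assayedSets[[nm]] <- aset
    col <- rep(NA_character_, nPatients)
    col[aset] <- "no"
    col[pos] <- "yes"
    tab[[nm]] <- col
  }
  list(table = tab,
       truth = list(positives = positives, assayed = assayedSets,
                    overlapMode = overlapMode, seed = as.integer(seed)))
}

defaultModelConfig <- function(startCodonOffset = 12L) {
  list(
    list(geneName = "MGMT", geneId = "ENSGSYN0001", chrom = "10", strand = "+",
         txStart = 131265000L, exonLengths = c(100L, 200L, 150L, 120L, 800L),
         intronLengths = c(1000L, 800L, 900L, 700L),
         utr5Len = 100L + startCodonOffset, cdsLen = 624L),
    list(geneName = "SAR1A", geneId = "ENSGSYN0002", chrom = "10", strand = "+",
         txStart = 71600000L, exonLengths = c(150L, 180L, 200L, 700L),
         intronLengths = c(1200L, 600L, 500L),
         utr5Len = 200L, cdsLen = 597L),
    list(geneName = "BTRC", geneId = "ENSGSYN0003", chrom = "10", strand = "+",
         txStart = 103113000L, exonLengths = c(250L, 183L, 300L, 900L),
         intronLengths = c(900L, 1100L, 450L),
         utr5Len = 133L, cdsLen = 1500L),
    list(geneName = "RPH3A", geneId = "ENSGSYN0004", chrom = "12", strand = "-",
         txStart = 113200000L, exonLengths = c(120L, 240L, 660L),
         intronLengths = c(700L, 850L),
         utr5Len = 180L, cdsLen = 702L)
  )
}

#' Generate synthetic transcript models
#'
#' Builds [TranscriptModel-class] fixtures from a declarative configuration
#' (exon/intron lengths, 5'UTR length in spliced coordinates, CDS length).
#' The default set contains an MGMT-like model whose exon-2 acceptor
#' boundary lies `startCodonOffset` nt (default 12) upstream of the start
#' codon, a partner whose first exon is entirely 5'UTR (promoter-swap donor),
#' a partner donating exactly 300 nt of CDS at its exon-2 donor boundary,
#' and a minus-strand partner.
#'
#' @param config list of per-transcript specs (see `defaultModelConfig` in
#'   the sources); each needs `geneName`, `chrom`, `strand`, `txStart` (5'
#'   end; the highest coordinate for minus-strand models), `exonLengths`,
#'   `intronLengths`, `utr5Len`, `cdsLen` (0 for non-coding).
#' @param startCodonOffset nt between the MGMT-like exon-2 acceptor boundary
#'   and the ATG in the default config.
#' @param seed unused by the deterministic construction; kept for interface
#'   symmetry with the other generators.
#' @return named list of [TranscriptModel-class] (by gene name).
#' @examples
#' models <- genGeneModels()
#' distanceToStartCodon(models$MGMT, IRanges::start(exons(models$MGMT))[2])
#' @export
genGeneModels <- function(config = NULL, startCodonOffset = 12L, seed = 1L) {
  if (is.null(config)) config <- defaultModelConfig(startCodonOffset)
  models <- lapply(config, function(cf) {
    nEx <- length(cf$exonLengths)
    stopifnot(length(cf$intronLengths) == nEx - 1L)
    mrnaLen <- sum(cf$exonLengths)
    coding <- cf$cdsLen > 0L
    if (coding && cf$utr5Len >= mrnaLen)
      stop("gene ", cf$geneName, ": CDS start falls outside the exons")
    if (coding && cf$utr5Len + cf$cdsLen > mrnaLen)
      stop("gene ", cf$geneName, ": CDS extends beyond the transcript")
    plus <- identical(cf$strand, "+")
    starts <- integer(nEx); ends <- integer(nEx)
    at <- as.integer(cf$txStart)
    for (i in seq_len(nEx)) {
      if (plus) {
        starts[i] <- at; ends[i] <- at + cf$exonLengths[i] - 1L
        at <- ends[i] + 1L + if (i < nEx) cf$intronLengths[i] else 0L
      } else {
        ends[i] <- at; starts[i] <- at - cf$exonLengths[i] + 1L
        at <- starts[i] - 1L - if (i < nEx) cf$intronLengths[i] else 0L
      }
    }
    m <- transcriptModel(
      transcriptId = paste0("T_", cf$geneName), geneId = cf$geneId,
      geneName = cf$geneName, chrom = cf$chrom, strand = cf$strand,
      exonStarts = starts, exonEnds = ends,
      biotype = if (coding) "protein_coding" else "lincRNA")
    if (coding) {
      m@cdsStartGenomic <- mrnaToGenomic(m, cf$utr5Len + 1L)
      m@cdsEndGenomic <- mrnaToGenomic(m, cf$utr5Len + cf$cdsLen)
      methods::validObject(m)
    }
    m
  })
  names(models) <- vapply(config, `[[`, character(1), "geneName")
  models
}

## Donor boundary (last base, transcription order) of exon j.
donorBoundary <- function(model, j) {
  ex <- exons(model)
  if (identical(txStrand(model), "+")) IRanges::end(ex)[j]
  else IRanges::start(ex)[j]
}

## Acceptor boundary (first base, transcription order) of exon j.
acceptorBoundary <- function(model, j) {
  ex <- exons(model)
  if (identical(txStrand(model), "+")) IRanges::start(ex)[j]
  else IRanges::end(ex)[j]
}

#' Generate a fusion-candidate table with planted truth
#'
#' Plants `nTrue` true acceptor-gene fusions (donor breakpoint on an exon
#' boundary of a partner model, acceptor breakpoint on the MGMT-like exon-2
#' acceptor boundary) plus decoys of each filtered class: a normal-tissue
#' read-through pair, a mitochondrial-gene fusion, an uncharacterised-gene
#' fusion, and a paralog pair. Each row carries its ground-truth label;
#' the expected structural category of each true event
#' (`five_prime_utr_swap` / `chimeric_in_frame` / `chimeric_out_of_frame`)
#' is computed arithmetically from the configuration at planting time.
#'
#' @param models model set from [genGeneModels()] (needs an `MGMT` entry).
#' @param nTrue number of true fusions to plant.
#' @param decoyConfig named integer vector of decoy counts per class
#'   (`normal_tissue`, `mitochondrial`, `uncharacterized`, `paralog`).
#' @param sampleIds optional pool of sample ids (default `"S001"...`;
#'   true events get distinct ids in order).
#' @param seed integer seed.
#' @return data.frame in the [readFusionCandidates()] layout plus
#'   `truth_class` (true / decoy class) and `truth_category` (NA for
#'   decoys).
#' @export
genFusionCandidates <- function(models, nTrue = 1L,
                                decoyConfig = c(normal_tissue = 1L,
                                                mitochondrial = 1L,
                                                uncharacterized = 1L,
                                                paralog = 1L),
                                sampleIds = NULL, seed = 1L) {
  stopifnot("MGMT" %in% names(models))
  set.seed(as.integer(seed))
  acceptor <- models$MGMT
  partners <- models[setdiff(names(models), "MGMT")]
  if (nTrue > 0L && length(partners) == 0L)
    stop("need at least one partner model to plant true fusions")
  rightPos <- acceptorBoundary(acceptor, 2L)
  offsetToAtg <- distanceToStartCodon(acceptor, rightPos)
  nRows <- nTrue + sum(decoyConfig)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(max(nRows, 1L)))

  rows <- list()
  for (i in seq_len(nTrue)) {
    pm <- partners[[(i - 1L) %% length(partners) + 1L]]
    ex <- exons(pm)
    j <- (i - 1L) %/% length(partners) %% max(1L, length(ex) - 1L) + 1L
    leftPos <- donorBoundary(pm, j)
    bpOffset <- sum(IRanges::width(ex)[seq_len(j)])
    atg <- if (isCoding(pm)) genomicToMrna(pm, cdsStartGenomic(pm)) else NA_integer_
    cdsNt <- if (!isCoding(pm) || bpOffset < atg) 0L else bpOffset - atg + 1L
    category <- if (cdsNt == 0L && offsetToAtg >= 0L) "five_prime_utr_swap"
                else if ((cdsNt + offsetToAtg) %% 3L == 0L) "chimeric_in_frame"
                else "chimeric_out_of_frame"
    rows[[length(rows) + 1L]] <- data.frame(
      fusion_name = paste0(geneName(pm), "--MGMT"),
      left_gene = geneName(pm), right_gene = "MGMT",
      junction_reads = sample(5:60, 1), spanning_frags = sample(2:30, 1),
      sample_id = sampleIds[i],
      left_chrom = chrom(pm), left_pos = leftPos, left_strand = txStrand(pm),
      right_chrom = chrom(acceptor), right_pos = rightPos,
      right_strand = txStrand(acceptor),
      truth_class = "true", truth_category = category,
      stringsAsFactors = FALSE)
  }

  decoyGene <- list(
    normal_tissue = c("TTTY15", "USP9Y"),
    mitochondrial = c("ATP5F1", "MT-CO1"),
    uncharacterized = c("GLRX3", "LOC101927374"),
    paralog = c("HSPA1A", "HSPA1B"))
  k <- nTrue
  for (cls in names(decoyConfig)) {
    for (d in seq_len(decoyConfig[[cls]])) {
      k <- k + 1L
      g <- decoyGene[[cls]]
      rows[[length(rows) + 1L]] <- data.frame(
        fusion_name = paste0(g[1], "--", g[2]),
        left_gene = g[1], right_gene = g[2],
        junction_reads = sample(5:60, 1), spanning_frags = sample(2:30, 1),
        sample_id = sampleIds[(k - 1L) %% length(sampleIds) + 1L],
        left_chrom = as.character(sample(1:22, 1)),
        left_pos = sample(1000000:2000000, 1), left_strand = "+",
        right_chrom = as.character(sample(1:22, 1)),
        right_pos = sample(1000000:2000000, 1), right_strand = "+",
        truth_class = cls, truth_category = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- readFusionCandidates(textConnectionStub())
    out$truth_class <- character(0)
    out$truth_category <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

## empty candidate table with the right columns
textConnectionStub <- function() {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(FUSION_TSV_COLUMNS, collapse = "\t"), tf)
  tf
}

#' Generate pileup base-count tables from planted genotypes
#'
#' Mutant patients receive variant reads at the configured heterozygous
#' allele fraction; wildtype patients receive none. Depth per site is either
#' constant or Poisson.
#'
#' @param genotypes data.frame with `sample_id`, `gene` and `genotype`
#'   (`"mutant"`/`"wildtype"`), one row per patient x hotspot.
#' @param depthLaw list: `dist` (`"constant"` or `"poisson"`), `depth`
#'   (fixed depth or Poisson mean), `vaf` (mutant allele fraction,
#'   default 0.5).
#' @param hotspots hotspot definition table (default [idhHotspots()]).
#' @param seed integer seed.
#' @return data.frame in the [readPileup()] layout.
#' @export
genPileups <- function(genotypes,
                       depthLaw = list(dist = "constant", depth = 50L, vaf = 0.5),
                       hotspots = idhHotspots(), seed = 1L) {
  stopifnot(all(c("sample_id", "gene", "genotype") %in% colnames(genotypes)),
            all(genotypes$genotype %in% c("mutant", "wildtype")))
  set.seed(as.integer(seed))
  vaf <- if (is.null(depthLaw$vaf)) 0.5 else depthLaw$vaf
  n <- nrow(genotypes)
  defIdx <- match(genotypes$gene, hotspots$gene)
  if (anyNA(defIdx))
    stop("no hotspot definition for gene(s): ",
         paste(unique(genotypes$gene[is.na(defIdx)]), collapse = ", "))
  depth <- switch(depthLaw$dist,
    constant = rep(as.integer(depthLaw$depth), n),
    poisson = stats::rpois(n, depthLaw$depth),
    stop("unknown depth law: ", depthLaw$dist))
  alt <- ifelse(genotypes$genotype == "mutant",
                stats::rbinom(n, depth, vaf), 0L)
  counts <- matrix(0L, nrow = n, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) {
    def <- hotspots[defIdx[i], ]
    counts[i, def$ref] <- depth[i] - alt[i]
    counts[i, def$alt] <- counts[i, def$alt] + alt[i]
  }
  data.frame(sample_id = genotypes$sample_id,
             chrom = hotspots$chrom[defIdx],
             pos = hotspots$pos[defIdx],
             ref = hotspots$ref[defIdx],
             counts,
             stringsAsFactors = FALSE)
}

#' Generate MGMT expression with class-dependent shifts
#'
#' Draws log2 expression as a class baseline plus Gaussian noise: patients
#' positive for an alteration named in `effects$shifts` receive that shift
#' (fusion-positive and promoter-hypomethylated patients up, hypermutated
#' patients down, in the defaults).
#'
#' @param cohortTable data.frame from [genCohort()] (alteration columns in
#'   yes/no/NA coding).
#' @param effects list: `baseline` (log2 units), `sd` (noise SD), and
#'   `shifts`, a named numeric vector of log2 mean shifts keyed by
#'   alteration column.
#' @param seed integer seed.
#' @return numeric vector of log2 expression values aligned with
#'   `cohortTable` rows.
#' @export
genExpression <- function(cohortTable,
                          effects = list(baseline = 4, sd = 1,
                                         shifts = c(fusion = 2,
                                                    hypomethylation = 2,
                                                    hypermutation = -2)),
                          seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(cohortTable)
  mu <- rep(effects$baseline, n)
  for (nm in names(effects$shifts)) {
    if (!nm %in% colnames(cohortTable)) next
    pos <- !is.na(cohortTable[[nm]]) & cohortTable[[nm]] == "yes"
    mu[pos] <- mu[pos] + effects$shifts[[nm]]
  }
  mu + stats::rnorm(n, 0, effects$sd)
}

#' Write synthetic inputs to disk
#'
#' Materialises one coherent synthetic study (cohort CSV, fusion TSV, gene
#' model GTF, pileup TSV, upstream-calls CSV) under `outdir`, in exactly the
#' dialects the readers consume.
#'
#' @param outdir output directory (created if needed).
#' @param nPatients,counts,assayed,overlapMode passed to [genCohort()].
#'   When `counts`/`assayed` are NULL they default to the reference study
#'   conditions (7/27/52 positives, methylation assayed in 136 of 252),
#'   scaled proportionally to `nPatients`.
#' @param nTrueFusions planted fusion count (each in a distinct patient).
#' @param idhMutants number of IDH1-mutant patients to plant (default: 94
#'   of 252, scaled).
#' @param idhUnassayable number of patients given sub-threshold depth (4
#'   reads) so their hotspot status is NA (default: 7 of 252, scaled).
#' @param depth pileup depth for assayable patients.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return named list of the file paths written, plus the ground truth.
#' @export
simulateStudy <- function(outdir, nPatients = 252L,
                          counts = NULL, assayed = NULL,
                          overlapMode = "disjoint",
                          nTrueFusions = NULL, idhMutants = NULL,
                          idhUnassayable = NULL, depth = 60L, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  nPatients <- as.integer(nPatients)
  ## default study conditions at the reference cohort scale (252 patients:
  ## 7 fusion / 27 hypermutated / 52 of 136 assayed hypomethylated,
  ## 94 IDH-mutant with 7 unassayable), scaled proportionally otherwise
  sc <- function(x) as.integer(round(nPatients * x / 252))
  if (is.null(counts))
    counts <- c(fusion = sc(7), hypermutation = sc(27),
                hypomethylation = sc(52))
  if (is.null(assayed))
    assayed <- c(fusion = nPatients, hypermutation = nPatients,
                 hypomethylation = sc(136))
  if (is.null(idhMutants)) idhMutants <- sc(94)
  if (is.null(idhUnassayable)) idhUnassayable <- sc(7)
  syn <- genCohort(nPatients, counts, assayed, overlapMode, seed = seed)
  tab <- syn$table

  ## fusion events: one per fusion-positive patient (per the cohort truth)
  models <- genGeneModels()
  fusPatients <- syn$truth$positives$fusion
  if (is.null(nTrueFusions)) nTrueFusions <- length(fusPatients)
  cand <- genFusionCandidates(models, nTrue = nTrueFusions,
                              sampleIds = tab$patient_id[fusPatients],
                              seed = seed + 1L)

  ## IDH genotypes: mutants and low-depth patients disjoint
  set.seed(seed + 2L)
  stopifnot(idhMutants + idhUnassayable <= nPatients)
  perm <- sample(nPatients)
  mutIdx <- perm[seq_len(idhMutants)]
  lowIdx <- perm[idhMutants + seq_len(idhUnassayable)]
  genotypes <- data.frame(sample_id = tab$patient_id, gene = "IDH1",
                          genotype = ifelse(seq_len(nPatients) %in% mutIdx,
                                            "mutant", "wildtype"),
                          stringsAsFactors = FALSE)
  pileHigh <- genPileups(genotypes[-lowIdx, , drop = FALSE],
                         depthLaw = list(dist = "constant", depth = depth,
                                         vaf = 0.5), seed = seed + 3L)
  pileLow <- genPileups(genotypes[lowIdx, , drop = FALSE],
                        depthLaw = list(dist = "constant", depth = 4L,
                                        vaf = 0.5), seed = seed + 4L)
  pileup <- rbind(pileHigh, pileLow)

  expr <- genExpression(tab, seed = seed + 5L)
  tab$mgmt_expression <- round(expr, 4)

  upstream <- data.frame(
    patient_id = tab$patient_id,
    codel_1p19q = ifelse(is.na(tab$hypermutation), "NA", "no"),
    hypermutation = ifelse(is.na(tab$hypermutation), "NA",
                           tab$hypermutation),
    stringsAsFactors = FALSE)

  paths <- list(
    cohort_csv = file.path(outdir, "cohort.csv"),
    fusion_tsv = file.path(outdir, "fusion_candidates.tsv"),
    gtf = file.path(outdir, "models.gtf"),
    pileup_tsv = file.path(outdir, "pileup.tsv"),
    upstream_csv = file.path(outdir, "upstream_calls.csv"))
  utils::write.csv(tab, paths$cohort_csv, row.names = FALSE)
  writeFusionCandidates(cand, paths$fusion_tsv)
  writeGtf(models, paths$gtf)
  utils::write.table(pileup, paths$pileup_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(upstream, paths$upstream_csv, row.names = FALSE)
  c(paths, list(truth = syn$truth, candidates = cand,
                idh_mutant_idx = sort(mutIdx), idh_na_idx = sort(lowIdx)))
}
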