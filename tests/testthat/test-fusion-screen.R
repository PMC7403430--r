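test_that("fusion candidate TSV parsing round-trips and validates schema", {
  models <- genGeneModels()
  cand <- genFusionCandidates(models, nTrue = 2, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeFusionCandidates(cand, tf)
  back <- readFusionCandidates(tf)
  expect_equal(nrow(back), nrow(cand))
  expect_equal(back$left_pos, cand$left_pos)
  expect_equal(back$right_strand, cand$right_strand)

  # breakpoint parsing
  bp <- parseBreakpoint("10:131265000:+")
  expect_equal(bp$chrom, "10")
  expect_equal(bp$pos, 131265000L)
  expect_equal(bp$strand, "+")

  # schema errors
  broken <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(tf)
  writeLines(c(paste(setdiff(colnames(tab), "RightGene"), collapse = "\t")),
             broken)
  expect_error(readFusionCandidates(broken), "RightGene")
  bad <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(tf)
  writeLines(c(lines[1], sub("^([^\t]*\t[^\t]*\t)[^\t]*", "\\1oops",
                             lines[2])), bad)
  expect_error(readFusionCandidates(bad), "breakpoint")
})

test_that("filtering removes each decoy class with the right audit reason", {
  models <- genGeneModels()
  cand <- genFusionCandidates(models, nTrue = 1, seed = 11)
  res <- filterCandidates(cand)
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$retained$truth_class, "true")
  aud <- as.data.frame(res$audit)
  expect_equal(aud$reason[match(cand$fusion_name, aud$fusion_name)],
               ifelse(cand$truth_class == "true", "retained",
                      cand$truth_class))
})

test_that("filters are monotone and idempotent, and empty input passes through", {
  models <- genGeneModels()
  cand <- genFusionCandidates(models, nTrue = 2, seed = 5)
  res1 <- filterCandidates(cand)
  expect_lte(nrow(res1$retained), nrow(cand))
  res2 <- filterCandidates(res1$retained)
  expect_equal(res2$retained, res1$retained)
  expect_true(all(res2$audit$reason == "retained"))

  empty <- cand[0, ]
  res0 <- filterCandidates(empty)
  expect_equal(nrow(res0$retained), 0L)
  expect_equal(nrow(res0$audit), 0L)
})

test_that("mitochondrial prefix rule catches MT- partners on either side", {
  row <- candidateRow("MT-CO1", "MT", 5000L, "+", "GENE2", "2", 1000L, "+")
  res <- filterCandidates(row)
  expect_equal(as.character(res$audit$reason), "mitochondrial")
})

test_that("5'UTR-swap fusions are recognised with intact acceptor domains", {
  models <- genGeneModels()
  # SAR1A-like donor: exon 1 (150 nt) entirely 5'UTR; MGMT acceptor at the
  # exon-2 boundary, 12 nt upstream of the ATG
  cand <- candidateRow("SAR1A", "10", IRanges::end(exons(models$SAR1A))[1], "+",
                       "MGMT", "10", IRanges::start(exons(models$MGMT))[2], "+")
  ann <- annotateFusion(cand, models$SAR1A, models$MGMT, mgmtDomains())
  expect_equal(ann@category, "five_prime_utr_swap")
  expect_equal(ann@partnerCdsNt, 0L)
  expect_equal(ann@rightOffsetToStartCodon, 12L)
  expect_true(ann@rightCdsIntact)
  expect_true(all(ann@domainsRetained))
  expect_true(all(ann@breakpointOnExonBoundary))
})

test_that("chimeric fusions are classified in/out of frame by contributed CDS", {
  models <- genGeneModels()
  mgmtE2 <- IRanges::start(exons(models$MGMT))[2]
  # BTRC-like donor at exon-2 donor boundary contributes 300 nt of CDS
  c300 <- candidateRow("BTRC", "10", IRanges::end(exons(models$BTRC))[2], "+",
                       "MGMT", "10", mgmtE2, "+")
  a300 <- annotateFusion(c300, models$BTRC, models$MGMT, mgmtDomains())
  expect_equal(a300@partnerCdsNt, 300L)
  expect_equal(a300@category, "chimeric_in_frame")
  expect_true(all(a300@domainsRetained))

  # a 301-nt contribution breaks the frame: donor exon 2 stretched by one base
  btrc301 <- models$BTRC
  IRanges::end(btrc301@exons)[2] <- IRanges::end(btrc301@exons)[2] + 1L
  c301 <- candidateRow("BTRC", "10", IRanges::end(exons(btrc301))[2], "+",
                       "MGMT", "10", mgmtE2, "+")
  a301 <- annotateFusion(c301, btrc301, models$MGMT, mgmtDomains())
  expect_equal(a301@partnerCdsNt, 301L)
  expect_equal(a301@category, "chimeric_out_of_frame")
  expect_false(any(a301@domainsRetained))
})

test_that("off-boundary or intronic breakpoints yield unresolved, not errors", {
  models <- genGeneModels()
  mgmtE2 <- IRanges::start(exons(models$MGMT))[2]
  internal <- candidateRow("SAR1A", "10",
                           IRanges::end(exons(models$SAR1A))[1] - 5L, "+",
                           "MGMT", "10", mgmtE2, "+")
  annI <- annotateFusion(internal, models$SAR1A, models$MGMT, mgmtDomains())
  expect_equal(annI@category, "unresolved")
  expect_match(annI@diagnostic, "boundary")

  intronic <- candidateRow("SAR1A", "10",
                           IRanges::end(exons(models$SAR1A))[1] + 10L, "+",
                           "MGMT", "10", mgmtE2, "+")
  annN <- annotateFusion(intronic, models$SAR1A, models$MGMT, mgmtDomains())
  expect_equal(annN@category, "unresolved")
  expect_match(annN@diagnostic, "outside exons")
})

test_that("every annotated fusion receives exactly one category", {
  models <- genGeneModels()
  cats <- c("five_prime_utr_swap", "chimeric_in_frame",
            "chimeric_out_of_frame", "unresolved")
  mgmtE2 <- IRanges::start(exons(models$MGMT))[2]
  for (pm in c("SAR1A", "BTRC", "RPH3A")) {
    for (j in seq_along(exons(models[[pm]]))) {
      ex <- exons(models[[pm]])
      pos <- if (txStrand(models[[pm]]) == "+") IRanges::end(ex)[j]
             else IRanges::start(ex)[j]
      cand <- candidateRow(pm, chrom(models[[pm]]), pos,
                           txStrand(models[[pm]]), "MGMT", "10", mgmtE2, "+")
      ann <- annotateFusion(cand, models[[pm]], models$MGMT, mgmtDomains())
      expect_true(ann@category %in% cats)
      expect_equal(sum(ann@category == cats), 1L)
    }
  }
})

test_that("planted structural classes are recovered exactly on clean data", {
  models <- genGeneModels()
  byGene <- selectRepresentativeTranscript(models)
  for (seed in c(2, 9, 23)) {
    cand <- genFusionCandidates(models, nTrue = 6, seed = seed)
    true <- cand[cand$truth_class == "true", ]
    for (i in seq_len(nrow(true))) {
      ann <- annotateFusion(true[i, ], byGene[[true$left_gene[i]]],
                            byGene[[true$right_gene[i]]], mgmtDomains())
      expect_equal(ann@category, true$truth_category[i],
                   info = paste(seed, true$fusion_name[i], i))
    }
  }
})

test_that("patient summary counts events once per patient and skips unknowns", {
  cohort <- data.frame(patient_id = sprintf("P%02d", 1:10))
  events <- data.frame(
    fusion_name = c("A--MGMT", "B--MGMT", "C--MGMT"),
    sample_id = c("P01", "P01", "P03"), stringsAsFactors = FALSE)
  s <- fusionPatientSummary(events, cohort)
  expect_equal(s$nFusions, 3L)
  expect_equal(s$nPatients, 2L)
  pp <- as.data.frame(s$perPatient)
  expect_equal(pp$fusion_positive[pp$patient_id == "P01"], "yes")
  expect_equal(pp$n_fusions[pp$patient_id == "P01"], 2L)

  # eight events across seven patients, as in a fusion-positive cohort
  ev8 <- data.frame(fusion_name = paste0("F", 1:8, "--MGMT"),
                    sample_id = c(sprintf("P%02d", 1:7), "P01"))
  s8 <- fusionPatientSummary(ev8, cohort)
  expect_equal(c(s8$nFusions, s8$nPatients), c(8L, 7L))

  expect_warning(
    s2 <- fusionPatientSummary(
      rbind(events, data.frame(fusion_name = "X--MGMT", sample_id = "NOPE")),
      cohort),
    "unknown sample")
  expect_equal(s2$nPatients, 2L)

  s0 <- fusionPatientSummary(events[0, ], cohort)
  expect_equal(c(s0$nFusions, s0$nPatients), c(0L, 0L))
})
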