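test_that("cohort generation hits the requested marginal counts exactly", {
  syn <- genCohort(252, counts = c(fusion = 7, hypermutation = 27,
                                   hypomethylation = 52),
                   assayed = c(fusion = 252, hypermutation = 252,
                               hypomethylation = 136),
                   overlapMode = "disjoint", seed = 1)
  tab <- syn$table
  expect_equal(nrow(tab), 252L)
  expect_equal(sum(tab$fusion == "yes", na.rm = TRUE), 7L)
  expect_equal(sum(tab$hypermutation == "yes", na.rm = TRUE), 27L)
  expect_equal(sum(tab$hypomethylation == "yes", na.rm = TRUE), 52L)
  expect_equal(sum(is.na(tab$hypomethylation)), 116L)
  # disjoint mode: pairwise-disjoint positive sets
  pos <- syn$truth$positives
  expect_equal(length(intersect(pos$fusion, pos$hypermutation)), 0L)
  expect_equal(length(intersect(pos$fusion, pos$hypomethylation)), 0L)
  expect_equal(length(intersect(pos$hypermutation, pos$hypomethylation)), 0L)
  # positives always within assayed
  for (nm in names(pos)) expect_true(all(pos[[nm]] %in% syn$truth$assayed[[nm]]))
})

test_that("cohort generation is deterministic and validates infeasible specs", {
  a <- genCohort(40, counts = c(A = 5, B = 8), overlapMode = "independent",
                 seed = 99)
  b <- genCohort(40, counts = c(A = 5, B = 8), overlapMode = "independent",
                 seed = 99)
  expect_identical(a, b)
  expect_error(genCohort(10, counts = c(A = 6, B = 6), overlapMode = "disjoint"),
               "infeasible")
  expect_error(genCohort(10, counts = c(A = 6), assayed = c(A = 4)),
               "count <= assayed")
  expect_error(genCohort(10, counts = c(A = 2), cohorts = c(X = 0.5, Y = 0.4)),
               "sum to 1")
})

test_that("nested overlap mode nests smaller positive sets in larger ones", {
  syn <- genCohort(50, counts = c(A = 20, B = 10, C = 5),
                   overlapMode = "nested", seed = 3)
  pos <- syn$truth$positives
  expect_true(all(pos$C %in% pos$B))
  expect_true(all(pos$B %in% pos$A))
})

test_that("default gene models include the 12-nt promoter-swap geometry", {
  models <- genGeneModels()
  mgmt <- models$MGMT
  e2 <- IRanges::start(exons(mgmt))[2]
  expect_equal(distanceToStartCodon(mgmt, e2), 12L)
  expect_equal(exonBoundaryClass(mgmt, e2), "acceptor_boundary")
  # configurable offset
  m20 <- genGeneModels(startCodonOffset = 20L)$MGMT
  expect_equal(distanceToStartCodon(m20, IRanges::start(exons(m20))[2]), 20L)
  # single-exon model with CDS from base 1 has no 5'UTR
  cfg <- list(list(geneName = "ONE", geneId = "G1", chrom = "1", strand = "+",
                   txStart = 1000L, exonLengths = 300L,
                   intronLengths = integer(0), utr5Len = 0L, cdsLen = 300L))
  one <- genGeneModels(cfg)$ONE
  expect_equal(genomicToMrna(one, cdsStartGenomic(one)), 1L)
  # CDS start outside the exons is rejected
  bad <- list(list(geneName = "BAD", geneId = "G2", chrom = "1", strand = "+",
                   txStart = 1000L, exonLengths = 100L,
                   intronLengths = integer(0), utr5Len = 150L, cdsLen = 30L))
  expect_error(genGeneModels(bad), "outside the exons")
})

test_that("fusion candidate generation labels truth and is seeded", {
  models <- genGeneModels()
  cand <- genFusionCandidates(models, nTrue = 1, seed = 8)
  expect_equal(nrow(cand), 5L)
  expect_equal(sum(cand$truth_class == "true"), 1L)
  expect_setequal(cand$truth_class,
                  c("true", "normal_tissue", "mitochondrial",
                    "uncharacterized", "paralog"))
  expect_true(startsWith(
    cand$right_gene[cand$truth_class == "mitochondrial"], "MT-"))
  # true breakpoints sit on exon boundaries of their models
  tru <- cand[cand$truth_class == "true", ]
  expect_equal(exonBoundaryClass(models[[tru$left_gene]], tru$left_pos),
               "donor_boundary")
  expect_equal(exonBoundaryClass(models$MGMT, tru$right_pos),
               "acceptor_boundary")
  expect_identical(cand, genFusionCandidates(models, nTrue = 1, seed = 8))
})

test_that("pileup generation respects genotype, depth law and seed", {
  g <- data.frame(sample_id = c("A", "B"), gene = "IDH1",
                  genotype = c("wildtype", "mutant"))
  p <- genPileups(g, list(dist = "constant", depth = 100L, vaf = 0.5), seed = 1)
  ref <- idhHotspots()$ref[1]; alt <- idhHotspots()$alt[1]
  expect_equal(p[[alt]][1], 0L)            # wildtype: no variant reads
  expect_equal(p[[ref]][1], 100L)
  expect_gt(p[[alt]][2], 0L)
  expect_equal(p[[ref]][2] + p[[alt]][2], 100L)
  expect_identical(p, genPileups(g, list(dist = "constant", depth = 100L,
                                         vaf = 0.5), seed = 1))

  # constant depth 4: every downstream call is NA
  p4 <- genPileups(g, list(dist = "constant", depth = 4L, vaf = 0.5), seed = 2)
  expect_true(all(is.na(callHotspots(p4)$status)))

  # allele-fraction concentration at depth 1000
  gm <- data.frame(sample_id = sprintf("M%03d", 1:200), gene = "IDH1",
                   genotype = "mutant")
  pm <- genPileups(gm, list(dist = "constant", depth = 1000L, vaf = 0.5),
                   seed = 3)
  vaf <- pm[[alt]] / 1000
  # per-site binomial(1000, 0.5) concentration: +/-0.05 is > 3 SD
  expect_gte(mean(vaf > 0.45 & vaf < 0.55), 0.99)
  expect_lt(abs(mean(vaf) - 0.5), 0.01)
})

test_that("expression shifts follow alteration classes and noise SD", {
  tab <- data.frame(fusion = rep(c("yes", "no"), each = 40),
                    hypermutation = rep(c("no", "yes"), each = 40))
  e <- genExpression(tab, effects = list(baseline = 4, sd = 0,
                                         shifts = c(fusion = 2,
                                                    hypermutation = -2)),
                     seed = 1)
  expect_equal(unique(e[1:40]), 6)     # fusion-positive, noise-free
  expect_equal(unique(e[41:80]), 2)    # hypermutated, noise-free
  # with shift +2 SD the rank-sum comparison separates the groups
  set.seed(2)
  rej <- vapply(1:100, function(s) {
    v <- genExpression(tab, effects = list(baseline = 4, sd = 1,
                                           shifts = c(fusion = 2)), seed = s)
    wilcoxonCompare(v[1:40], v[41:80])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("a simulated study is coherent across all emitted files", {
  d <- withr::local_tempdir()
  sim <- simulateStudy(d, nPatients = 60,
                       counts = c(fusion = 3, hypermutation = 6,
                                  hypomethylation = 10),
                       assayed = c(fusion = 60, hypermutation = 60,
                                   hypomethylation = 30),
                       idhMutants = 20, idhUnassayable = 4, seed = 5)
  cohort <- read.csv(sim$cohort_csv)
  expect_equal(nrow(cohort), 60L)
  cand <- readFusionCandidates(sim$fusion_tsv)
  expect_true(all(file.exists(unlist(sim[1:5]))))
  # fusion sample ids are exactly the fusion-positive patients
  fusIds <- cohort$patient_id[which(cohort$fusion == "yes")]
  expect_setequal(intersect(cand$sample_id, fusIds), fusIds)
  # pileup covers everyone; unassayable patients get depth 4
  pile <- readPileup(sim$pileup_tsv)
  expect_equal(nrow(pile), 60L)
  calls <- callHotspots(pile)
  expect_equal(sum(is.na(calls$status)), 4L)
  expect_equal(sum(!is.na(calls$status) & calls$status == "mutant"), 20L)
})
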