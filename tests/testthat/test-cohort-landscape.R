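test_that("RPKM is the standard length- and depth-normalised transform", {
  expect_equal(rpkm(100, 2000, 5e7), 1)
  expect_equal(rpkm(0, 1500, 1e7), 0)
  expect_equal(rpkm(200, 2000, 5e7), 2 * rpkm(100, 2000, 5e7))
  expect_error(rpkm(10, 0, 1e7), "positive")
  expect_error(rpkm(10, 1000, 0), "positive")
})

test_that("within-cohort Z-scores are computed per cohort, NA for singletons", {
  z <- cohortZscore(c(10, 20, 30), rep("A", 3))
  expect_equal(z, c(-1, 0, 1))
  expect_true(is.na(cohortZscore(5, "A")))
  # two cohorts processed independently, each re-centred
  z2 <- cohortZscore(c(10, 20, 30, 1000, 2000, 3000),
                     rep(c("A", "B"), each = 3))
  expect_equal(z2, rep(c(-1, 0, 1), 2))
  # idempotence: re-standardising Z-scores changes nothing
  expect_equal(cohortZscore(z2, rep(c("A", "B"), each = 3)), z2)
  # zero-SD cohort -> NA
  expect_true(all(is.na(cohortZscore(c(3, 3, 3), rep("A", 3)))))
})

test_that("Clopper-Pearson interval matches the inverse-Beta form and binom.test", {
  ci <- binomialCI(7, 252, 0.95)
  # frozen against an independent inverse-Beta computation
  expect_equal(ci$lower, 0.011239515099823, tolerance = 1e-10)
  expect_equal(ci$upper, 0.056392852721056, tolerance = 1e-10)
  for (x in c(0, 1, 13, 252)) {
    ci <- binomialCI(x, 252)
    bt <- binom.test(x, 252)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
  }
  expect_equal(binomialCI(0, 10)$lower, 0)
  expect_equal(binomialCI(10, 10)$upper, 1)
  expect_error(binomialCI(11, 10), "x <= n")
})

test_that("the 95% exact interval is conservative at the fusion frequency", {
  set.seed(31)
  draws <- rbinom(2000, 252, 0.03)
  covered <- vapply(draws, function(x) {
    ci <- binomialCI(x, 252)
    ci$lower <= 0.03 && 0.03 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("Fisher exact enrichment is two-sided and symmetric", {
  expect_equal(fisherEnrichment(1, 1, 1, 1), 1)
  expect_equal(fisherEnrichment(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisherEnrichment(5, 0, 0, 5), fisherEnrichment(0, 5, 5, 0))
  expect_error(fisherEnrichment(0, 0, 0, 0), "all-zero")
})

test_that("Wilcoxon comparison: exact for small n (ties included), else normal", {
  expect_equal(wilcoxonCompare(1:3, 4:6)$p.value, 0.1)  # enumeration of C(6,3)
  expect_equal(wilcoxonCompare(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  expect_equal(wilcoxonCompare(1:3, 4:6)$p.value,
               wilcoxonCompare(4:6, 1:3)$p.value)
  # tie-free exact branch agrees with the reference implementation
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(wilcoxonCompare(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-sample branch: close to the reference normal approximation
  x <- rnorm(30); y <- rnorm(35) + 0.5
  expect_equal(wilcoxonCompare(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE)$p.value, tolerance = 1e-12)
  expect_error(wilcoxonCompare(numeric(0), 1:3), "non-empty")
})

test_that("landscape assembly joins all call sets with NA for missing assays", {
  syn <- genCohort(20, counts = c(fusion = 2, hypermutation = 3,
                                  hypomethylation = 4),
                   assayed = c(fusion = 20, hypermutation = 20,
                               hypomethylation = 10),
                   overlapMode = "disjoint", seed = 4)
  tab <- syn$table
  idh <- data.frame(patient_id = tab$patient_id,
                    idh_status = rep(c("mutant", "wildtype"), 10))
  fus <- fusionPatientSummary(
    data.frame(fusion_name = "X--MGMT",
               sample_id = tab$patient_id[syn$truth$positives$fusion]), tab)
  ls <- assembleLandscape(tab, idhCalls = idh, fusionSummary = fus,
                          expression = rnorm(20, 5))
  df <- as.data.frame(patients(ls))
  expect_equal(df$patient_id, sort(tab$patient_id))
  expect_equal(sum(df$fusion_positive == "yes"), 2L)
  expect_equal(sum(is.na(df$hypomethylation)), 10L)
  expect_equal(sum(df$idh_status == "mutant"), 10L)
  expect_true(all(!is.na(df$mgmt_z)))

  dup <- rbind(tab, tab[1, ])
  expect_error(assembleLandscape(dup), "duplicate")
})

test_that("frequency tallies use assay-specific denominators", {
  syn <- genCohort(252, counts = c(fusion = 7, hypermutation = 27,
                                   hypomethylation = 52),
                   assayed = c(fusion = 252, hypermutation = 252,
                               hypomethylation = 136),
                   overlapMode = "disjoint", seed = 2)
  ls <- assembleLandscape(syn$table)
  freq <- tallyFrequencies(ls)
  get <- function(a, col) freq[freq$alteration == a, col]
  expect_equal(get("hypermutation", "positive"), 27)
  expect_equal(get("hypermutation", "assayed"), 252)
  expect_equal(get("hypermutation", "percent"), 10.7)
  expect_equal(get("hypomethylation", "assayed"), 136)
  expect_equal(get("hypomethylation", "percent"), 38.2)

  # an IDH column with 94 mutants of 245 assayed prints as 38.4%
  tab <- data.frame(patient_id = sprintf("P%03d", 1:252), cohort = "A",
                    idh_status = c(rep("mutant", 94), rep("wildtype", 151),
                                   rep(NA, 7)))
  f2 <- tallyFrequencies(assembleLandscape(tab))
  expect_equal(f2$positive, 94)
  expect_equal(f2$assayed, 245)
  expect_equal(f2$percent, 38.4)

  # all-NA column: denominator 0, percent NA
  tab$idh_status <- NA_character_
  f3 <- tallyFrequencies(assembleLandscape(tab),
                         alterations = list(idh = list(column = "idh_status",
                                                       positive = "mutant")))
  expect_equal(f3$assayed, 0)
  expect_true(is.na(f3$percent))
})
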