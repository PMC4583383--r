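test_that("cohort spec validation rejects impossible inputs", {
  expect_error(cohortSpec(nCases = -1), "nCases")
  badFreqs <- cohortSpec()@caseFreqs
  badFreqs[] <- 0.3
  expect_error(cohortSpec(caseFreqs = badFreqs), "sums to more than 1")
  expect_error(generateCohort(cohortSpec(nCases = 0, nControls = 0,
                                         nFamily = 0)),
               "positive")
})

test_that("sampled diplotype frequencies converge to the spec frequencies", {
  spec <- cohortSpec(nCases = 10000L, nControls = 0L, nFamily = 0L, seed = 3L)
  cohort <- generateCohort(spec)
  freqs <- spec@caseFreqs
  for (cat in names(freqs)) {
    phat <- mean(cohort$diplotype == cat)
    se <- sqrt(freqs[[cat]] * (1 - freqs[[cat]]) / 10000)
    expect_lt(abs(phat - freqs[[cat]]), 3 * se + 1e-12)
  }
  # published case frequency of the DQ2.5 homozygote at the study n
  s473 <- cohortSpec(nCases = 473L, nControls = 0L, nFamily = 0L, seed = 5L)
  phat <- mean(generateCohort(s473)$diplotype == "DQ2.5/DQ2.5")
  expect_lt(abs(phat - 0.125), 3 * sqrt(0.125 * 0.875 / 473))
})

test_that("a degenerate diplotype distribution is reproduced exactly", {
  freqs <- cohortSpec()@caseFreqs
  freqs[] <- 0
  freqs["DQ8/DQ8"] <- 1
  spec <- cohortSpec(nCases = 200L, nControls = 0L, nFamily = 0L,
                     caseFreqs = freqs, seed = 2L)
  expect_true(all(generateCohort(spec)$diplotype == "DQ8/DQ8"))
})

test_that("rs3130484 genotypes follow Hardy-Weinberg proportions", {
  spec <- cohortSpec(nCases = 10000L, nControls = 0L, nFamily = 0L,
                     msh5MafCases = 0.5, seed = 7L)
  counts <- table(factor(generateCohort(spec)$rs3130484, levels = 0:2))
  expected <- c(0.25, 0.5, 0.25)   # exact multinomial proportions at maf 0.5
  for (i in 1:3) {
    se <- sqrt(expected[i] * (1 - expected[i]) / 10000)
    expect_lt(abs(counts[i] / 10000 - expected[i]), 3 * se)
  }
})

test_that("sampled diplotypes survive the round trip through the caller", {
  cohort <- generateCohort(cohortSpec(seed = 13L))
  called <- callCohortDiplotypes(cohort)
  expect_identical(called$diplotype, cohort$diplotype)
})

test_that("rs9272346 carriage tracks DQ2.5 carriage as configured", {
  # r^2 = 1: carriage identical
  spec1 <- cohortSpec(nCases = 2000L, nControls = 2000L, nFamily = 0L,
                      dqa1R2 = 1, seed = 17L)
  cohort <- generateCohort(spec1)
  expect_identical(cohort$rs9272346 >= 1L, cohort$rs2187668 >= 1L)
  # r^2 = 0: independent (phi coefficient within Monte-Carlo error of zero)
  spec0 <- cohortSpec(nCases = 20000L, nControls = 0L, nFamily = 0L,
                      dqa1R2 = 0, seed = 19L)
  cohort0 <- generateCohort(spec0)
  phi <- cor(cohort0$rs9272346 >= 1L, cohort0$rs2187668 >= 1L)
  expect_lt(abs(phi), 3 / sqrt(20000))
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  expect_identical(generateCohort(cohortSpec(seed = 23L)),
                   generateCohort(cohortSpec(seed = 23L)))
  cohort <- generateCohort(cohortSpec(seed = 23L))
  expect_identical(assignPools(cohort, seed = 5L),
                   assignPools(cohort, seed = 5L))
})

test_that("pool assignment respects the design constraints", {
  cohort <- generateCohort(cohortSpec(nCases = 400L, nControls = 300L,
                                      nFamily = 0L, seed = 29L))
  design <- assignPools(cohort, nCasePools = 9L, nControlPools = 6L,
                        sizeRange = c(33L, 44L), seed = 1L)
  sizes <- lengths(design@poolMembers)
  expect_length(design@poolIds, 15L)
  expect_true(all(sizes >= 33L & sizes <= 44L))
  members <- unlist(design@poolMembers)
  expect_false(anyDuplicated(members) > 0)
  caseMembers <- unlist(design@poolMembers[design@poolGroup == "case"])
  expect_true(all(caseMembers %in% cohort$sample_id[cohort$group == "CD"]))

  # forced assignment: one pool of exactly 33 takes all 33 cases
  small <- generateCohort(cohortSpec(nCases = 33L, nControls = 40L,
                                     nFamily = 0L, seed = 31L))
  one <- assignPools(small, nCasePools = 1L, nControlPools = 1L,
                     sizeRange = c(33L, 33L), seed = 1L)
  expect_setequal(one@poolMembers[["case1"]],
                  small$sample_id[small$group == "CD"])

  # sizing error names the deficit: 4 pools need >= 132 of the 100 cases
  hundred <- generateCohort(cohortSpec(nCases = 100L, nControls = 300L,
                                       nFamily = 0L, seed = 37L))
  expect_error(assignPools(hundred, nCasePools = 4L, nControlPools = 6L,
                           sizeRange = c(33L, 44L), seed = 1L),
               "need at least 132, have 100")
})

test_that("pool intensities encode the true pool allele fraction", {
  cohort <- cohortFromCounts(c("DQ2.5/DQ2.5" = 3L), c(OTHER = 3L),
                             msh5 = c(0L, 1L, 2L))
  design <- poolDesign(list(case1 = cohort$sample_id[1:3],
                            ctrl1 = cohort$sample_id[4:6]),
                       c("case", "control"))
  quiet <- arrayNoiseModel(0, 0, seed = 1L)
  pie <- simulatePoolIntensities(design, cohort, noise = quiet)
  ras <- SummarizedExperiment::assay(computeRas(pie), "ras")
  # all members homozygous at rs2187668: pure minor-allele pool
  expect_equal(ras["rs2187668", "case1"], 1.0)
  # dosages {0,1,2} average to fraction 0.5
  expect_equal(ras["rs3130484", "case1"], 0.5)
  expect_equal(ras["rs3130484", "ctrl1"], 0.5)
  # unknown member is a lookup error
  bad <- poolDesign(list(case1 = c("nobody")), "case")
  expect_error(simulatePoolIntensities(bad, cohort, noise = quiet),
               "absent")
})

test_that("RAS noise has the configured standard deviation", {
  # 1000 replicate arrays of a 0.5-fraction pool, no array bias
  pie <- simulateScanPools(nNull = 1L, planted = NULL, nCasePools = 500L,
                           nControlPools = 500L,
                           noise = arrayNoiseModel(0.03, 0),
                           nullFracRange = c(0.5, 0.5), seed = 41L)
  ras <- SummarizedExperiment::assay(computeRas(pie), "ras")
  expect_lt(abs(sd(ras[1, ]) - 0.03), 0.003)
  expect_lt(abs(mean(ras[1, ]) - 0.5), 0.005)
})

test_that("simulated RAS is truncated to the unit interval", {
  pie <- simulateScanPools(nNull = 200L, planted = NULL, nCasePools = 5L,
                           nControlPools = 5L,
                           noise = arrayNoiseModel(0.5, 0.2),
                           nullFracRange = c(0.01, 0.99), seed = 43L)
  ras <- SummarizedExperiment::assay(computeRas(pie), "ras")
  expect_true(all(ras >= 0 & ras <= 1))
})
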