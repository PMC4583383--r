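test_that("RAS is the A-channel share of the total signal", {
  A <- matrix(c(100, 50, 30, 0), 4, 3)
  B <- matrix(c(0, 50, 90, 0), 4, 3)
  pie <- pieFromChannels(A, B, c("case", "case", "control"))
  expect_message(ras <- computeRas(pie), "zero total signal")
  r <- SummarizedExperiment::assay(ras, "ras")
  expect_equal(unname(r[1:3, 1]), c(1, 0.5, 0.25))
  expect_true(all(is.na(r[4, ])))
  expect_identical(S4Vectors::metadata(ras)$n_missing, 3L)
})

test_that("MAPD matches hand-computed values in both dialects", {
  # constant log2 ratio: all differences zero
  flat <- rasFromMatrix(matrix(0.8, 5, 2), c("case", "control"))
  expect_equal(computeMapd(flat, "a01"), 0)

  # log2 ratios (0, 1, 0) in position order: r = 0.5, 2/3, 0.5
  r <- matrix(c(0.5, 2 / 3, 0.5, 0.5, 0.5, 0.5), 3, 2)
  colnames(r) <- c("x", "y")
  ras <- rasFromMatrix(r, c("case", "control"))
  expect_equal(computeMapd(ras, "x", mode = "consecutive"), 1)  # median{1,1}
  expect_equal(computeMapd(ras, "x", mode = "allpairs"), 1)     # median{1,1,0}

  tiny <- rasFromMatrix(matrix(0.5, 1, 2), c("case", "control"))
  expect_error(computeMapd(tiny, "a01"), "fewer than 2")
})

test_that("MAPD orders SNPs by genome coordinate, not row order", {
  # rows stored out of order; in position order the log2 ratios are 0,1,0
  r <- matrix(c(2 / 3, 0.5, 0.5), 3, 2)
  colnames(r) <- c("x", "y")
  ras <- rasFromMatrix(r, c("case", "control"),
                       pos = c(2000L, 1000L, 3000L))
  expect_equal(computeMapd(ras, "x", mode = "consecutive"), 1)
})

test_that("the noisiest control array is removed, never a case array", {
  set.seed(61)
  n <- 60
  base <- matrix(0.5, n, 8)
  colnames(base) <- c(paste0("case", 1:4), paste0("ctrl", 1:4))
  jitter <- matrix(rnorm(n * 8, 0, 0.01), n, 8,
                   dimnames = dimnames(base))
  jitter[, "ctrl2"] <- jitter[, "ctrl2"] * 6    # noisy control
  jitter[, "case1"] <- jitter[, "case1"] * 10   # even noisier case
  ras <- rasFromMatrix(pmin(pmax(base + jitter, 0), 1),
                       rep(c("case", "control"), each = 4))
  out <- dropWorstControl(ras)
  expect_identical(S4Vectors::metadata(out)$removed_array, "ctrl2")
  expect_true(all(paste0("case", 1:4) %in% colnames(out)))

  # identical arrays: tie broken by id order, logged
  flat <- rasFromMatrix(matrix(0.5, 10, 4),
                        rep(c("case", "control"), each = 2))
  expect_message(out2 <- dropWorstControl(flat), "tie")
  expect_identical(S4Vectors::metadata(out2)$removed_array, "a03")

  one <- rasFromMatrix(matrix(0.5, 10, 3), c("case", "case", "control"))
  expect_error(dropWorstControl(one), "at least 2 control arrays")
})

test_that("Welch scan handles identity and degenerate-variance cases", {
  r <- matrix(rep(c(0.4, 0.5, 0.6), each = 6), 3, 6, byrow = TRUE)
  ras <- rasFromMatrix(r, rep(c("case", "control"), each = 3))
  scan <- welchScan(ras)
  expect_equal(scan$t, c(0, 0, 0))
  expect_equal(scan$p, c(1, 1, 1))

  # zero variance with unequal means: limiting p of 0, logged
  r2 <- matrix(rep(c(0.6, 0.6, 0.6, 0.4, 0.4, 0.4), 2), 2, 6, byrow = TRUE)
  ras2 <- rasFromMatrix(r2, rep(c("case", "control"), each = 3))
  expect_message(scan2 <- welchScan(ras2), "zero variance")
  expect_equal(scan2$p, c(0, 0))
})

test_that("a clear group separation is detected at high significance", {
  set.seed(67)
  case <- 0.6 + rnorm(4, 0, 1e-6)
  ctrl <- 0.4 + rnorm(3, 0, 1e-6)
  ras <- rasFromMatrix(matrix(c(case, ctrl), 1, 7),
                       rep(c("case", "control"), c(4, 3)))
  expect_lt(welchScan(ras)$p, 1e-6)
})

test_that("Welch statistics agree with the reference implementation", {
  set.seed(71)
  n <- 200
  r <- matrix(runif(n * 15), n, 15)
  grp <- rep(c("case", "control"), c(9, 6))
  scan <- welchScan(rasFromMatrix(r, grp))
  for (i in seq_len(n)) {
    ref <- t.test(r[i, grp == "case"], r[i, grp == "control"])
    expect_equal(scan$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(scan$df[i], unname(ref$parameter), tolerance = 1e-12)
    expect_equal(scan$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("scan adjustment equals the brute-force step-up oracle", {
  set.seed(73)
  r <- matrix(runif(50 * 10), 50, 10)
  scan <- welchScan(rasFromMatrix(r, rep(c("case", "control"), each = 5)))
  expect_equal(scan$p_adj, oracleBH(scan$p), tolerance = 1e-12)
  # adjusted p >= raw p, <= 1, and BH preserves the raw-p ranking
  expect_true(all(scan$p_adj >= scan$p & scan$p_adj <= 1))
  expect_true(all(diff(scan$p_adj[order(scan$p)]) >= 0))
})

test_that("hit selection applies the thresholds and the locus window", {
  scan <- data.frame(
    snp = c("hit", "near", "far", "pair1", "pair2", "null"),
    chrom = c("6", "6", "6", "2", "2", "3"),
    pos = c(1e6, 1e6 + 1e5, 1e6 + 2e5, 5e6, 5e6 + 1e5, 1e6),
    p = c(1e-9, 1e-6, 1e-6, 1e-6, 5e-6, 0.5)
  )
  hits <- selectHits(scan)
  expect_identical(hits$hits$snp, "hit")
  expect_identical(hits$support$snp, "near")       # 100 kb away, within 150 kb
  expect_setequal(hits$otherLoci$snp, c("pair1", "pair2"))
  expect_false("far" %in% hits$support$snp)        # 200 kb away

  none <- selectHits(transform(scan, p = pmax(p, 1e-7)))
  expect_identical(nrow(none$hits), 0L)
})

test_that("Manhattan and QQ tables transform p-values correctly", {
  scan <- data.frame(snp = c("a", "b"), chrom = c("1", "1"),
                     pos = c(1L, 2L), p = c(1, 5e-8))
  tab <- manhattanTable(scan)
  expect_equal(tab$neglog10p, c(0, 7.301), tolerance = 1e-4)

  # uniform p-values sit near the QQ diagonal
  set.seed(79)
  u <- data.frame(snp = paste0("s", 1:2000), chrom = "1",
                  pos = seq_len(2000), p = runif(2000))
  qq <- qqTable(u)
  mid <- qq$expected < 2          # away from the noisy extreme tail
  expect_lt(max(abs(qq$observed[mid] - qq$expected[mid])), 0.35)
})

test_that("two-pass scan reports both p-value columns", {
  set.seed(83)
  pie <- simulateScanPools(nNull = 40L,
                           planted = data.frame(snp_id = "plant", chrom = "6",
                                                pos = 3e7, frac_case = 0.9,
                                                frac_control = 0.1),
                           nCasePools = 5L, nControlPools = 4L,
                           noise = arrayNoiseModel(0.01, 0.005), seed = 83L)
  res <- allelotypeScan(pie)
  expect_true(all(c("p_complete", "p_adj", "p_filtered") %in%
                  colnames(res$table)))
  expect_match(res$removed_array, "^ctrl")
  plant <- res$table[res$table$snp == "plant", ]
  expect_lt(plant$p_complete, 1e-6)
  expect_lt(plant$p_filtered, 1e-6)
})
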