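#' @include AllClasses.R
NULL

#' Compute relative allele signals from two-channel intensities
#'
#' RAS = A / (A + B) per SNP per array. Cells where both channels are zero
#' are flagged missing (NA) and counted in the returned object's metadata;
#' they are excluded from downstream tests at that SNP.
#'
#' @param pie a [PoolIntensityExperiment-class].
#' @return a [RasExperiment-class] with metadata entry `n_missing`.
#' @export
computeRas <- function(pie) {
  validObject(pie)
  A <- SummarizedExperiment::assay(pie, "A")
  B <- SummarizedExperiment::assay(pie, "B")
  tot <- A + B
  ras <- A / tot
  ras[tot == 0] <- NA_real_
  nMissing <- sum(tot == 0)
  if (nMissing) message(nMissing, " SNP x array cells had zero total signal")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ras = ras),
    rowRanges = SummarizedExperiment::rowRanges(pie),
    colData = SummarizedExperiment::colData(pie),
    metadata = list(n_missing = nMissing))
  new("RasExperiment", se)
}

## log2 allele ratio from RAS: log2(A/B) = log2(r / (1 - r)), epsilon-floored
log2Ratio <- function(r, eps = 1e-6) {
  log2(pmax(r, eps) / pmax(1 - r, eps))
}

#' Per-chip MAPD noise metric
#'
#' Median of absolute differences of per-SNP log2 allele ratios on one chip.
#' The default dialect takes differences between markers consecutive in
#' genome order (the Affymetrix convention); the `"allpairs"` dialect takes
#' all pairwise differences.
#'
#' @param ras a [RasExperiment-class].
#' @param array array id (a column name); if NULL, all arrays (named vector).
#' @param mode `"consecutive"` or `"allpairs"`.
#' @return numeric MAPD value(s).
#' @export
computeMapd <- function(ras, array = NULL, mode = c("consecutive", "allpairs")) {
  mode <- match.arg(mode)
  validObject(ras)
  r <- SummarizedExperiment::assay(ras, "ras")
  rr <- SummarizedExperiment::rowRanges(ras)
  ord <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
  r <- r[ord, , drop = FALSE]
  one <- function(id) {
    v <- r[, id]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stopf("array '%s' has fewer than 2 usable SNPs", id)
    lr <- log2Ratio(v)
    d <- if (mode == "consecutive") diff(lr) else as.numeric(stats::dist(lr))
    median(abs(d))
  }
  if (!is.null(array)) {
    if (!array %in% colnames(r)) stopf("unknown array id '%s'", array)
    return(one(array))
  }
  vapply(colnames(r), one, numeric(1))
}

#' Drop the noisiest control array
#'
#' Removes the control array with the highest MAPD, mirroring the study's
#' second comparison pass ("after removing one control sample according to
#' higher MAPD"). Ties are broken by array id order and logged. Case arrays
#' are never touched.
#'
#' @param ras a [RasExperiment-class] with at least two control arrays.
#' @param mode MAPD dialect, passed to [computeMapd()].
#' @return the [RasExperiment-class] without that array; the removed id is
#'   recorded in `metadata(ras)$removed_array`.
#' @export
dropWorstControl <- function(ras, mode = c("consecutive", "allpairs")) {
  mode <- match.arg(mode)
  validObject(ras)
  ctrl <- colnames(ras)[ras$group == "control"]
  if (length(ctrl) < 2L) {
    stopf("need at least 2 control arrays to remove one (have %d)",
          length(ctrl))
  }
  mapd <- computeMapd(ras, mode = mode)[ctrl]
  worst <- max(mapd)
  cand <- sort(names(mapd)[mapd == worst])
  if (length(cand) > 1L) {
    message("MAPD tie between ", paste(cand, collapse = ", "),
            "; removing first by id order")
  }
  removed <- cand[1L]
  out <- ras[, setdiff(colnames(ras), removed)]
  out <- new("RasExperiment", out)
  S4Vectors::metadata(out)$removed_array <- removed
  S4Vectors::metadata(out)$removed_mapd <- unname(worst)
  out
}

## vectorised two-sided Welch t-test across the rows of a RAS matrix
welchRows <- function(x, y) {
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- apply(x, 1, stats::var, na.rm = TRUE)
  v2 <- apply(y, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  ## degenerate variances: equal means -> no evidence (p = 1);
  ## unequal means with zero variance -> limiting p = 0
  zerovar <- se2 == 0
  same <- zerovar & (m1 == m2)
  t[same] <- 0; p[same] <- 1; df[same] <- n1[same] + n2[same] - 2
  diffr <- zerovar & (m1 != m2)
  if (any(diffr)) {
    message(sum(diffr), " SNP(s) with zero variance and unequal means: p -> 0")
    t[diffr] <- sign(m1 - m2)[diffr] * Inf
    p[diffr] <- 0; df[diffr] <- n1[diffr] + n2[diffr] - 2
  }
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, t = t, df = df, p = p)
}

#' Welch t-test scan of case vs control pool allele ratios
#'
#' Per SNP, a two-sided Welch t-test (Welch-Satterthwaite degrees of freedom)
#' compares RAS across case arrays with RAS across control arrays;
#' Benjamini-Hochberg adjustment is applied over all tested SNPs. SNPs with
#' fewer than two valid values in either group are reported untested.
#'
#' @param ras a [RasExperiment-class].
#' @return data.frame (one row per SNP): `snp`, `chrom`, `pos`, `n_case`,
#'   `n_control`, `mean_ras_case`, `mean_ras_control`, `t`, `df`, `p`,
#'   `p_adj`, `tested`.
#' @export
welchScan <- function(ras) {
  validObject(ras)
  r <- SummarizedExperiment::assay(ras, "ras")
  grp <- ras$group
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L) {
    stopf("need at least 2 case and 2 control arrays")
  }
  w <- welchRows(r[, grp == "case", drop = FALSE],
                 r[, grp == "control", drop = FALSE])
  rr <- SummarizedExperiment::rowRanges(ras)
  out <- data.frame(
    snp = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    n_case = w$n1, n_control = w$n2,
    mean_ras_case = w$m1, mean_ras_control = w$m2,
    t = w$t, df = w$df, p = w$p,
    tested = w$n1 >= 2L & w$n2 >= 2L,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$t[!out$tested] <- NA_real_
  out$df[!out$tested] <- NA_real_
  out$p[!out$tested] <- NA_real_
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Two-pass allelotyping scan
#'
#' Runs the Welch scan on the complete array set and again after removing the
#' highest-MAPD control array, mirroring the study's two comparisons; merges
#' both p-value columns.
#'
#' @param pie a [PoolIntensityExperiment-class].
#' @param mapdMode MAPD dialect for the filtering pass.
#' @return list with elements `complete`, `filtered` (the per-pass scan
#'   data.frames), `table` (merged: `p_complete`, `p_adj`, `p_filtered`) and
#'   `removed_array`.
#' @export
allelotypeScan <- function(pie, mapdMode = c("consecutive", "allpairs")) {
  mapdMode <- match.arg(mapdMode)
  ras <- computeRas(pie)
  complete <- welchScan(ras)
  filteredRas <- dropWorstControl(ras, mode = mapdMode)
  filtered <- welchScan(filteredRas)
  merged <- complete[, c("snp", "chrom", "pos", "t", "df")]
  merged$p_complete <- complete$p
  merged$p_adj <- complete$p_adj
  merged$p_filtered <- filtered$p[match(merged$snp, filtered$snp)]
  list(complete = complete, filtered = filtered, table = merged,
       removed_array = S4Vectors::metadata(filteredRas)$removed_array)
}

#' Select genome-wide hits and supporting loci
#'
#' Reports (a) SNPs with raw p below the genome-wide threshold, (b) for each
#' hit, supporting SNPs with p below the support threshold within the locus
#' window (same chromosome, closed distance bound), and (c) loci elsewhere
#' containing more than one supporting SNP.
#'
#' @param scan data.frame from [welchScan()] (columns `snp`, `chrom`, `pos`,
#'   `p`).
#' @param gwThreshold genome-wide significance threshold (default 5e-8).
#' @param supportThreshold support threshold (default 1e-5).
#' @param locusWindow window in bp (default 150000).
#' @return list with data.frames `hits`, `support` (hit id + supporting SNP)
#'   and `otherLoci` (locus id per multi-SNP non-hit locus).
#' @export
selectHits <- function(scan, gwThreshold = 5e-8, supportThreshold = 1e-5,
                       locusWindow = 150000) {
  ok <- !is.na(scan$p)
  hits <- scan[ok & scan$p < gwThreshold, , drop = FALSE]
  sup <- scan[ok & scan$p < supportThreshold, , drop = FALSE]
  supportRows <- list()
  nearHit <- rep(FALSE, nrow(sup))
  for (i in seq_len(nrow(hits))) {
    near <- sup$chrom == hits$chrom[i] &
      abs(sup$pos - hits$pos[i]) <= locusWindow & sup$snp != hits$snp[i]
    nearHit <- nearHit | (sup$chrom == hits$chrom[i] &
                          abs(sup$pos - hits$pos[i]) <= locusWindow)
    if (any(near)) {
      supportRows[[hits$snp[i]]] <- data.frame(hit = hits$snp[i],
                                               sup[near, , drop = FALSE])
    }
  }
  support <- if (length(supportRows)) do.call(rbind, c(supportRows,
                                                       make.row.names = FALSE))
             else data.frame()
  ## cluster the remaining supporting SNPs into loci by the same window
  rest <- sup[!nearHit, , drop = FALSE]
  rest <- rest[order(rest$chrom, rest$pos), , drop = FALSE]
  otherLoci <- data.frame()
  if (nrow(rest)) {
    locus <- cumsum(c(TRUE, diff(rest$pos) > locusWindow |
                            rest$chrom[-1] != rest$chrom[-nrow(rest)]))
    rest$locus <- locus
    counts <- table(locus)
    keep <- rest$locus %in% as.integer(names(counts)[counts > 1L])
    otherLoci <- rest[keep, , drop = FALSE]
  }
  list(hits = hits, support = support, otherLoci = otherLoci)
}

#' Manhattan-ready table
#'
#' @param scan data.frame from [welchScan()].
#' @param pColumn which p-value column to transform.
#' @return data.frame (`snp`, `chrom`, `pos`, `neglog10p`) sorted by genome
#'   coordinate.
#' @export
manhattanTable <- function(scan, pColumn = "p") {
  out <- data.frame(snp = scan$snp, chrom = scan$chrom, pos = scan$pos,
                    neglog10p = -log10(scan[[pColumn]]),
                    stringsAsFactors = FALSE)
  suppressWarnings(numChrom <- as.numeric(out$chrom))
  ord <- order(ifelse(is.na(numChrom), Inf, numChrom), out$chrom, out$pos)
  out[ord, , drop = FALSE]
}

#' QQ table of observed vs expected -log10 p
#'
#' Expected quantiles are `-log10((i - 0.5) / n)` over the sorted tested
#' p-values.
#'
#' @param scan data.frame from [welchScan()].
#' @param pColumn which p-value column to use.
#' @return data.frame with `expected` and `observed` columns.
#' @export
qqTable <- function(scan, pColumn = "p") {
  p <- sort(scan[[pColumn]][!is.na(scan[[pColumn]])])
  n <- length(p)
  ## both columns descending: smallest p first
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Basic Manhattan plot
#'
#' @param scan data.frame from [welchScan()].
#' @param file optional PNG path; if NULL, plots to the active device.
#' @param gwThreshold threshold line (default 5e-8).
#' @return the plotted table, invisibly.
#' @export
plotManhattan <- function(scan, file = NULL, gwThreshold = 5e-8) {
  tab <- manhattanTable(scan)
  tab <- tab[is.finite(tab$neglog10p) | !is.na(tab$neglog10p), , drop = FALSE]
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  chrom <- factor(tab$chrom, levels = unique(tab$chrom))
  x <- seq_len(nrow(tab))
  graphics::plot(x, tab$neglog10p, pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[1 + as.integer(chrom) %% 2],
                 xlab = "genome position (ordered SNPs)",
                 ylab = expression(-log[10](p)))
  graphics::abline(h = -log10(gwThreshold), col = "red", lty = 2)
  invisible(tab)
}
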