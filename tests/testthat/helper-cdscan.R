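# shared fixtures and independent oracles, built in code

# cohort with diplotype category counts fixed exactly (no sampling);
# counts: named vector over dqCategories()
cohortFromCounts <- function(caseCounts, controlCounts,
                             msh5 = 0L, dqa1 = 0L) {
  mk <- function(counts, group) {
    diplo <- rep(names(counts), times = counts)
    n <- length(diplo)
    if (n == 0L) return(NULL)
    data.frame(sample_id = sprintf("%s_%04d", group, seq_len(n)),
               group = group, diplotypeToTagDosages(diplo),
               rs3130484 = rep_len(msh5, n), rs9272346 = rep_len(dqa1, n),
               diplotype = diplo, stringsAsFactors = FALSE)
  }
  rbind(mk(caseCounts, "CD"), mk(controlCounts, "control"))
}

# published diplotype frequency table as rounded counts of 473 cases / 714
# controls (percent columns 12.5/23.6/9.4/1.5/0.7/0 and
# 2.8/2.5/1.8/2.5/0.5/1.5, remainder OTHER)
table1CaseCounts <- function() {
  n <- c(59L, 112L, 44L, 7L, 3L, 0L)
  counts <- c(n, 473L - sum(n))
  names(counts) <- dqCategories()
  counts
}

table1ControlCounts <- function() {
  n <- c(20L, 18L, 13L, 18L, 4L, 11L)
  counts <- c(n, 714L - sum(n))
  names(counts) <- dqCategories()
  counts
}

# independent diplotype oracle: expand haplotype labels by dosage in priority
# order and keep the first two copies
oracleDiplotype <- function(d25, d8, d22) {
  if (d25 == 2 && d8 == 2 && d22 == 2) return(NA_character_)  # rejected input
  copies <- rep(c("DQ2.5", "DQ8", "DQ2.2"), times = c(d25, d8, d22))
  if (length(copies) < 2) return("OTHER")
  pair <- copies[1:2]
  if (pair[1] == pair[2]) paste(pair[1], pair[1], sep = "/")
  else paste(pair, collapse = "/")
}

# brute-force Benjamini-Hochberg step-up: adjusted p for the k-th smallest
# p-value is min over j >= k of (m/j) p_(j), capped at 1 (the defining
# cumulative minimum, computed literally)
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adjSorted <- vapply(seq_len(m), function(k) {
    min(1, min(sorted[k:m] * m / (k:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adjSorted
  adj
}

# RasExperiment built directly from a RAS matrix (rows get consecutive
# positions on one chromosome unless chrom/pos given)
rasFromMatrix <- function(ras, groups, chrom = NULL, pos = NULL) {
  n <- nrow(ras)
  if (is.null(rownames(ras))) rownames(ras) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(ras))) colnames(ras) <- sprintf("a%02d", seq_len(ncol(ras)))
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(rr) <- rownames(ras)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ras = ras),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(pool_id = colnames(ras), group = groups,
                                   row.names = colnames(ras)))
  new("RasExperiment", se)
}

pieFromChannels <- function(A, B, groups, chrom = NULL, pos = NULL) {
  n <- nrow(A)
  if (is.null(rownames(A))) {
    rownames(A) <- rownames(B) <- sprintf("s%03d", seq_len(n))
  }
  if (is.null(colnames(A))) {
    colnames(A) <- colnames(B) <- sprintf("a%02d", seq_len(ncol(A)))
  }
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(rr) <- rownames(A)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(A = A, B = B),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(pool_id = colnames(A), group = groups,
                                   row.names = colnames(A)))
  new("PoolIntensityExperiment", se)
}

# hand-built PoolDesign
poolDesign <- function(members, groups) {
  new("PoolDesign", poolIds = names(members),
      poolGroup = stats::setNames(groups, names(members)),
      poolMembers = members)
}
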