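#' @include AllClasses.R
NULL

## Diplotype category frequencies of the genotyped cohorts (percent / 100):
## cases n = 473, controls n = 714. OTHER absorbs the remaining mass
## (cases 52.3%, controls 88.4%). Family defaults sit midway between the two,
## supporting the replication-contrast analyses.
defaultCaseFreqs <- function() {
  c("DQ2.5/DQ2.5" = 0.125, "DQ2.5/DQ2.2" = 0.236, "DQ2.5/DQ8" = 0.094,
    "DQ8/DQ2.2" = 0.015, "DQ8/DQ8" = 0.007, "DQ2.2/DQ2.2" = 0.000)
}

defaultControlFreqs <- function() {
  c("DQ2.5/DQ2.5" = 0.028, "DQ2.5/DQ2.2" = 0.025, "DQ2.5/DQ8" = 0.018,
    "DQ8/DQ2.2" = 0.025, "DQ8/DQ8" = 0.005, "DQ2.2/DQ2.2" = 0.015)
}

defaultFamilyFreqs <- function() {
  (defaultCaseFreqs() + defaultControlFreqs()) / 2
}

#' Construct a cohort specification
#'
#' Defaults reproduce the genotyped study cohorts: 473 CD patients and 714
#' unrelated controls with the published diplotype category frequencies, plus
#' 357 healthy CD family members at intermediate frequencies. The rs3130484
#' minor-allele frequencies default to values calibrated so that the allelic
#' case-control odds ratio is near 6.1 (and family-vs-control near 3.1); the
#' rs9272346 carriage correlation with DQ2.5 carriage defaults to r^2 = 0.5
#' (moderate linkage).
#'
#' @param nCases,nControls,nFamily cohort sizes.
#' @param caseFreqs,controlFreqs,familyFreqs named frequency vectors over the
#'   six diplotype categories (remainder is `OTHER`).
#' @param msh5MafCases,msh5MafControls,msh5MafFamily rs3130484 minor-allele
#'   frequencies per group.
#' @param dqa1R2 squared correlation between rs9272346 carriage and DQ2.5
#'   carriage, in \[0,1\].
#' @param dqa1HomFrac probability an rs9272346 carrier is homozygous.
#' @param seed RNG seed.
#' @return a validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nCases = 100, nControls = 150, seed = 7)
#' cohort <- generateCohort(spec)
#' table(cohort$group)
#' @export
cohortSpec <- function(nCases = 473L, nControls = 714L, nFamily = 357L,
                       caseFreqs = defaultCaseFreqs(),
                       controlFreqs = defaultControlFreqs(),
                       familyFreqs = defaultFamilyFreqs(),
                       msh5MafCases = 0.318, msh5MafControls = 0.071,
                       msh5MafFamily = 0.19,
                       dqa1R2 = 0.5, dqa1HomFrac = 0.2, seed = 1L) {
  new("CohortSpec",
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      nFamily = as.integer(nFamily),
      caseFreqs = caseFreqs[tableCategories()],
      controlFreqs = controlFreqs[tableCategories()],
      familyFreqs = familyFreqs[tableCategories()],
      msh5MafCases = msh5MafCases, msh5MafControls = msh5MafControls,
      msh5MafFamily = msh5MafFamily,
      dqa1R2 = dqa1R2, dqa1HomFrac = dqa1HomFrac, seed = as.integer(seed))
}

#' Map a diplotype category to tag-SNP dosages
#'
#' The exact inverse of the diplotype caller: DQ2.5 copies become rs2187668
#' dosage, DQ8 copies rs7454108 dosage, and DQ2.2 copies are written to both
#' of its tag SNPs (rs7775228 and rs2395182), so re-calling recovers the
#' category for every sample. `OTHER` maps to zero dosage at all four tags.
#'
#' @param categories character vector of diplotype categories.
#' @return data.frame with the four tag-SNP dosage columns.
#' @export
diplotypeToTagDosages <- function(categories) {
  bad <- setdiff(unique(categories), dqCategories())
  if (length(bad)) stopf("unknown diplotype category: %s",
                         paste(bad, collapse = ", "))
  copies <- list(
    "DQ2.5/DQ2.5" = c(2L, 0L, 0L), "DQ2.5/DQ2.2" = c(1L, 0L, 1L),
    "DQ2.5/DQ8"  = c(1L, 1L, 0L), "DQ8/DQ2.2"  = c(0L, 1L, 1L),
    "DQ8/DQ8"    = c(0L, 2L, 0L), "DQ2.2/DQ2.2" = c(0L, 0L, 2L),
    "OTHER"      = c(0L, 0L, 0L)
  )
  m <- do.call(rbind, copies[categories])
  data.frame(rs2187668 = m[, 1L], rs7454108 = m[, 2L],
             rs7775228 = m[, 3L], rs2395182 = m[, 3L])
}

sampleGroup <- function(n, group, freqs, maf, spec) {
  if (n == 0L) {
    return(data.frame(sample_id = character(), group = character(),
                      rs2187668 = integer(), rs7454108 = integer(),
                      rs7775228 = integer(), rs2395182 = integer(),
                      rs3130484 = integer(), rs9272346 = integer(),
                      diplotype = character(), stringsAsFactors = FALSE))
  }
  probs <- c(freqs, OTHER = 1 - sum(freqs))
  diplo <- sample(names(probs), n, replace = TRUE, prob = probs)
  tags <- diplotypeToTagDosages(diplo)
  msh5 <- rbinom(n, 2L, maf)           # Hardy-Weinberg at the group MAF
  ## rs9272346 carriage: with weight w = sqrt(r^2) copy the DQ2.5-carriage
  ## indicator, otherwise draw an independent carrier with the same marginal;
  ## the phi coefficient of the two indicators is then w, i.e. r^2 as asked.
  dq25carrier <- as.integer(tags$rs2187668 >= 1L)
  pCarr <- sum(freqs[hlaRiskCategories()])
  w <- sqrt(spec@dqa1R2)
  copy <- rbinom(n, 1L, w) == 1L
  indep <- rbinom(n, 1L, pCarr)
  dqa1carrier <- ifelse(copy, dq25carrier, indep)
  dqa1 <- dqa1carrier * (1L + rbinom(n, 1L, spec@dqa1HomFrac))
  data.frame(
    sample_id = sprintf("%s_%04d", group, seq_len(n)), group = group,
    tags, rs3130484 = msh5, rs9272346 = as.integer(dqa1),
    diplotype = diplo, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort of individual genotypes
#'
#' Samples one diplotype category per individual from the group-specific
#' frequencies, converts it to tag-SNP dosages via [diplotypeToTagDosages()],
#' draws the rs3130484 dosage from the group minor-allele frequency under
#' Hardy-Weinberg equilibrium, and draws the rs9272346 dosage correlated with
#' DQ2.5 carriage at the configured r^2. Deterministic given the spec seed.
#'
#' @param spec a [CohortSpec-class].
#' @return a genotype table: data.frame with columns `sample_id`, `group`
#'   (`"CD"`, `"control"`, `"family"`), minor-allele dosages at the six study
#'   SNPs, and the simulated `diplotype` (the simulation truth; downstream
#'   callers re-derive it from the dosages).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  if (spec@nCases + spec@nControls + spec@nFamily <= 0L) {
    stopf("cohort size must be positive")
  }
  set.seed(spec@seed)
  rbind(
    sampleGroup(spec@nCases, "CD", spec@caseFreqs, spec@msh5MafCases, spec),
    sampleGroup(spec@nControls, "control", spec@controlFreqs,
                spec@msh5MafControls, spec),
    sampleGroup(spec@nFamily, "family", spec@familyFreqs,
                spec@msh5MafFamily, spec)
  )
}

#' Assign samples to DNA pools
#'
#' Stratifies cases and controls into disjoint pools whose sizes are drawn
#' uniformly from `sizeRange`, mirroring the study's pooling design (nine case
#' and six control pools of 33-44 samples). When the genotype table carries
#' `sex` and/or `age_band` columns, samples are ordered by those strata before
#' being cut into pools (pools homogeneous in sex/age, as in the study);
#' otherwise assignment is random. Family samples are never pooled.
#'
#' @param table genotype table from [generateCohort()] (or read from disk).
#' @param nCasePools,nControlPools number of pools per group.
#' @param sizeRange integer pair; inclusive pool-size bounds.
#' @param seed RNG seed.
#' @return a [PoolDesign-class].
#' @export
assignPools <- function(table, nCasePools = 9L, nControlPools = 6L,
                        sizeRange = c(33L, 44L), seed = 1L) {
  stopifnot(length(sizeRange) == 2L, sizeRange[1] <= sizeRange[2])
  set.seed(seed)
  design <- list(case = list(group = "CD", n = nCasePools, prefix = "case"),
                 control = list(group = "control", n = nControlPools,
                                prefix = "ctrl"))
  ids <- character(); grp <- character(); members <- list()
  for (d in design) {
    if (d$n == 0L) next
    pool <- table[table$group == d$group, , drop = FALSE]
    need <- d$n * sizeRange[1]
    if (nrow(pool) < need) {
      stopf("not enough %s samples to fill %d pools: need at least %d, have %d",
            d$group, d$n, need, nrow(pool))
    }
    sizeChoices <- seq(sizeRange[1], sizeRange[2])   # may be length 1
    sizes <- sizeChoices[sample.int(length(sizeChoices), d$n, replace = TRUE)]
    while (sum(sizes) > nrow(pool)) {       # shrink the largest pool to fit
      k <- which.max(sizes)
      sizes[k] <- sizes[k] - 1L
    }
    strata <- intersect(c("sex", "age_band"), colnames(pool))
    ord <- sample(nrow(pool))               # random within (or without) strata
    if (length(strata)) {
      ord <- ord[do.call(order, pool[ord, strata, drop = FALSE])]
    }
    chosen <- pool$sample_id[ord][seq_len(sum(sizes))]
    split_idx <- rep(seq_len(d$n), times = sizes)
    for (i in seq_len(d$n)) {
      id <- sprintf("%s%d", d$prefix, i)
      ids <- c(ids, id)
      grp[id] <- if (d$group == "CD") "case" else "control"
      members[[id]] <- chosen[split_idx == i]
    }
  }
  new("PoolDesign", poolIds = ids, poolGroup = grp[ids], poolMembers = members)
}

#' Construct an array-noise model
#'
#' @param rasNoiseSd per-SNP-per-array additive RAS noise SD (default 0.03,
#'   a typical pooled-array allelotyping error).
#' @param arrayBiasSd per-array additive offset SD (default 0.01).
#' @param seed RNG seed.
#' @return an [ArrayNoiseModel-class].
#' @export
arrayNoiseModel <- function(rasNoiseSd = 0.03, arrayBiasSd = 0.01, seed = 1L) {
  new("ArrayNoiseModel", rasNoiseSd = rasNoiseSd, arrayBiasSd = arrayBiasSd,
      seed = as.integer(seed))
}

## shared assembly of a PoolIntensityExperiment from a matrix of true pool
## allele fractions; applies array bias + noise, truncates, splits channels
buildIntensities <- function(frac, snpInfo, groups, noise,
                             totalSignal = 2000) {
  nArr <- ncol(frac)
  bias <- rnorm(nArr, 0, noise@arrayBiasSd)
  eps <- matrix(rnorm(length(frac), 0, noise@rasNoiseSd), nrow(frac), nArr)
  ras <- clamp01(frac + rep(bias, each = nrow(frac)) + eps)
  A <- ras * totalSignal
  B <- (1 - ras) * totalSignal
  dimnames(A) <- dimnames(B) <- dimnames(frac)
  rr <- GenomicRanges::GRanges(
    seqnames = snpInfo$chrom,
    ranges = IRanges::IRanges(start = snpInfo$pos, width = 1L),
    snp_id = snpInfo$snp_id
  )
  names(rr) <- snpInfo$snp_id
  cd <- S4Vectors::DataFrame(pool_id = colnames(frac), group = groups,
                             row.names = colnames(frac))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(A = A, B = B), rowRanges = rr, colData = cd)
  new("PoolIntensityExperiment", se)
}

#' Simulate pooled-array two-channel intensities from individual genotypes
#'
#' For each SNP x pool-array, the true pool allele fraction is the mean
#' minor-allele dosage of the pool members divided by two; for panel SNPs not
#' carried per-individual the pool's allele count is drawn binomially from the
#' group population MAF. The emitted A/B channel pair encodes
#' RAS = A/(A+B) = truncate(fraction + array bias + noise).
#'
#' @param design a [PoolDesign-class].
#' @param table genotype table containing every pool member.
#' @param noise an [ArrayNoiseModel-class].
#' @param extraPanel optional data.frame (`snp_id`, `chrom`, `pos`,
#'   `maf_case`, `maf_control`) of additional SNPs simulated from population
#'   MAFs.
#' @param panel SNP annotation for the genotyped SNPs; defaults to
#'   [defaultSnpPanel()].
#' @param totalSignal constant A+B per SNP per array.
#' @return a [PoolIntensityExperiment-class].
#' @export
simulatePoolIntensities <- function(design, table, noise = arrayNoiseModel(),
                                    extraPanel = NULL,
                                    panel = defaultSnpPanel(),
                                    totalSignal = 2000) {
  validObject(design)
  unknown <- setdiff(unlist(design@poolMembers), table$sample_id)
  if (length(unknown)) {
    stopf("pool members absent from the genotype table: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  }
  set.seed(noise@seed)
  snps <- intersect(panel$snp_id, colnames(table))
  rownames(table) <- table$sample_id
  nPools <- length(design@poolIds)
  frac <- matrix(NA_real_, length(snps), nPools,
                 dimnames = list(snps, design@poolIds))
  for (j in seq_len(nPools)) {
    members <- table[design@poolMembers[[j]], snps, drop = FALSE]
    frac[, j] <- colMeans(as.matrix(members)) / 2
  }
  info <- panel[match(snps, panel$snp_id), c("snp_id", "chrom", "pos")]
  if (!is.null(extraPanel)) {
    stopifnot(all(c("snp_id", "maf_case", "maf_control") %in%
                  colnames(extraPanel)))
    if (any(extraPanel$maf_case < 0 | extraPanel$maf_case > 1 |
            extraPanel$maf_control < 0 | extraPanel$maf_control > 1)) {
      stopf("panel MAFs must lie in [0,1]")
    }
    sizes <- lengths(design@poolMembers)
    ef <- matrix(NA_real_, nrow(extraPanel), nPools,
                 dimnames = list(extraPanel$snp_id, design@poolIds))
    for (j in seq_len(nPools)) {
      maf <- if (design@poolGroup[j] == "case") extraPanel$maf_case
             else extraPanel$maf_control
      ef[, j] <- rbinom(nrow(extraPanel), 2L * sizes[j], maf) / (2 * sizes[j])
    }
    frac <- rbind(frac, ef)
    info <- rbind(info, extraPanel[, c("snp_id", "chrom", "pos")])
  }
  buildIntensities(frac, info, unname(design@poolGroup), noise, totalSignal)
}

#' Simulate a genome-scale pooled allelotyping experiment
#'
#' Forward model for the pooled scan at the pool-fraction level: each null SNP
#' receives one true allele fraction shared by every pool in both groups
#' (drawn uniformly from `nullFracRange`), and each planted SNP receives fixed
#' group-specific fractions; measurement error (array bias + RAS noise) is the
#' only difference between arrays. Null SNPs are laid out on chromosomes 1-22
#' at 200 kb spacing; planted SNPs carry their own coordinates.
#'
#' @param nNull number of null SNPs.
#' @param planted data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `frac_case`, `frac_control`; may be empty/NULL.
#' @param nCasePools,nControlPools arrays per group.
#' @param noise an [ArrayNoiseModel-class].
#' @param nullFracRange range of the null SNPs' shared allele fractions.
#' @param seed RNG seed.
#' @return a [PoolIntensityExperiment-class].
#' @export
simulateScanPools <- function(nNull = 10000L, planted = NULL,
                              nCasePools = 9L, nControlPools = 6L,
                              noise = arrayNoiseModel(),
                              nullFracRange = c(0.05, 0.95), seed = 1L) {
  set.seed(seed)
  nPlanted <- if (is.null(planted)) 0L else nrow(planted)
  poolIds <- c(sprintf("case%d", seq_len(nCasePools)),
               sprintf("ctrl%d", seq_len(nControlPools)))
  groups <- rep(c("case", "control"), c(nCasePools, nControlPools))
  nullFrac <- runif(nNull, nullFracRange[1], nullFracRange[2])
  frac <- matrix(rep(nullFrac, length(poolIds)), nNull, length(poolIds),
                 dimnames = list(sprintf("null_%05d", seq_len(nNull)),
                                 poolIds))
  chrom <- rep_len(as.character(seq_len(22L)), nNull)
  pos <- 1e6 + 200000 * (seq_len(nNull) %/% 22L)
  info <- data.frame(snp_id = rownames(frac), chrom = chrom, pos = pos,
                     stringsAsFactors = FALSE)
  if (nPlanted) {
    pf <- matrix(NA_real_, nPlanted, length(poolIds),
                 dimnames = list(planted$snp_id, poolIds))
    pf[, groups == "case"] <- planted$frac_case
    pf[, groups == "control"] <- planted$frac_control
    frac <- rbind(frac, pf)
    info <- rbind(info, data.frame(snp_id = planted$snp_id,
                                   chrom = as.character(planted$chrom),
                                   pos = planted$pos,
                                   stringsAsFactors = FALSE))
  }
  buildIntensities(frac, info, groups, noise)
}
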