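#' @include AllClasses.R
NULL

#' Default SNP panel of the six study variants
#'
#' The four HLA tag SNPs plus the two GWAS hits, with chromosome-6 1-based
#' positions (GRCh37) and the allele each SNP tags. The tagged allele is the
#' allele counted by the dosage columns; the VCF reader orients genotypes to
#' it, flipping REF/ALT as needed.
#'
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `tagged`, `role`.
#' @export
defaultSnpPanel <- function() {
  data.frame(
    snp_id = c("rs2187668", "rs7454108", "rs7775228", "rs2395182",
               "rs3130484", "rs9272346"),
    chrom = "6",
    pos = c(32605884L, 32681631L, 32658079L, 32413957L,
            31715882L, 32604372L),
    ref = c("C", "T", "T", "G", "C", "G"),
    tagged = c("T", "C", "C", "T", "T", "A"),
    role = c("HLA-tag", "HLA-tag", "HLA-tag", "HLA-tag",
             "GWAS-hit", "GWAS-hit"),
    stringsAsFactors = FALSE
  )
}

dosageColumns <- function(panel = defaultSnpPanel()) panel$snp_id

#' Write / read a genotype table as TSV
#'
#' Canonical tab-separated representation: `sample_id`, `group`, one dosage
#' column per panel SNP, plus any extra columns (e.g. `diplotype`). Values
#' round-trip exactly.
#'
#' @param table genotype table.
#' @param path file path.
#' @return `readGenotypesTsv` returns the genotype table.
#' @export
writeGenotypesTsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
readGenotypesTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = NA)
}

#' Write a genotype table as minimal VCF v4.2
#'
#' One record per panel SNP on chromosome 6 (1-based positions), GT-only
#' FORMAT, one column per sample. The ALT allele is the panel's tagged
#' allele, so dosage d becomes GT with d ALT alleles; missing dosages become
#' `./.`. Group labels are preserved in a `##SAMPLE_GROUPS` header line.
#'
#' @param table genotype table.
#' @param path file path.
#' @param panel SNP panel (see [defaultSnpPanel()]).
#' @return the path, invisibly.
#' @export
writeGenotypesVcf <- function(table, path, panel = defaultSnpPanel()) {
  snps <- intersect(panel$snp_id, colnames(table))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cdscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##SAMPLE_GROUPS=",
           paste(table$sample_id, table$group, sep = ":", collapse = ",")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$sample_id), collapse = "\t")
  ), con)
  for (s in snps) {
    row <- panel[panel$snp_id == s, ]
    d <- table[[s]]
    calls <- ifelse(is.na(d), "./.", gt[d + 1L])
    writeLines(paste(c(row$chrom, row$pos, s, row$ref, row$tagged, ".",
                       "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

vcfDosage <- function(gtField) {
  gt <- sub(":.*", "", gtField)
  ifelse(gt %in% c("./.", ".|.", "."), NA_integer_,
         vapply(strsplit(gt, "[/|]"), function(a) {
           sum(as.integer(a) > 0L)
         }, integer(1)))
}

#' Read genotypes from VCF or TSV
#'
#' VCF records are matched to the panel by SNP id; dosages are oriented to
#' the panel's tagged allele, flipping when the tagged allele is REF (flips
#' are logged). An allele mismatch with the panel is an error naming the
#' SNP. TSV files are read as written by [writeGenotypesTsv()].
#'
#' @param path file path (`.vcf` or anything else treated as TSV).
#' @param panel SNP panel.
#' @return genotype table; panel SNPs absent from a VCF are reported via a
#'   message and omitted.
#' @export
readGenotypes <- function(path, panel = defaultSnpPanel()) {
  if (!grepl("\\.vcf(\\.gz)?$", path)) {
    return(readGenotypesTsv(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gtm <- vcf@gt[, -1, drop = FALSE]   # drop FORMAT column
  samples <- colnames(gtm)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  ## recover group labels if our header line is present
  meta <- grep("^##SAMPLE_GROUPS=", vcf@meta, value = TRUE)
  if (length(meta) == 1L) {
    pairs <- strsplit(strsplit(sub("^##SAMPLE_GROUPS=", "", meta),
                               ",")[[1]], ":")
    grp <- setNames(vapply(pairs, `[`, "", 2L), vapply(pairs, `[`, "", 1L))
    out$group <- unname(grp[samples])
  }
  absent <- setdiff(panel$snp_id, fix$ID)
  if (length(absent)) {
    message("panel SNP(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  for (s in intersect(panel$snp_id, fix$ID)) {
    i <- match(s, fix$ID)
    prow <- panel[panel$snp_id == s, ]
    d <- vcfDosage(gtm[i, ])
    if (identical(fix$ALT[i], prow$tagged)) {
      ## dosage already counts the tagged allele
    } else if (identical(fix$REF[i], prow$tagged)) {
      message("orienting ", s, ": tagged allele is REF, flipping dosage")
      d <- 2L - d
    } else {
      stopf("allele mismatch for %s: VCF %s/%s does not carry tagged allele %s",
            s, fix$REF[i], fix$ALT[i], prow$tagged)
    }
    out[[s]] <- d
  }
  out
}

#' Write / read pooled-array intensities as TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, then one `<array>_A` / `<array>_B`
#' pair per array. Array group labels are encoded in the array id prefix
#' (`case*` / `ctrl*`) and recovered on read.
#'
#' @param pie a [PoolIntensityExperiment-class].
#' @param path file path.
#' @return `readPoolIntensities` returns a [PoolIntensityExperiment-class].
#' @export
writePoolIntensities <- function(pie, path) {
  rr <- SummarizedExperiment::rowRanges(pie)
  A <- SummarizedExperiment::assay(pie, "A")
  B <- SummarizedExperiment::assay(pie, "B")
  out <- data.frame(snp_id = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    stringsAsFactors = FALSE)
  for (j in colnames(A)) {
    out[[paste0(j, "_A")]] <- A[, j]
    out[[paste0(j, "_B")]] <- B[, j]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoolIntensities
#' @export
readPoolIntensities <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  aCols <- grep("_A$", colnames(tab), value = TRUE)
  arrays <- sub("_A$", "", aCols)
  A <- as.matrix(tab[, paste0(arrays, "_A")])
  B <- as.matrix(tab[, paste0(arrays, "_B")])
  dimnames(A) <- dimnames(B) <- list(tab$snp_id, arrays)
  groups <- ifelse(grepl("^case", arrays), "case", "control")
  rr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$pos, width = 1L),
                               snp_id = tab$snp_id)
  names(rr) <- tab$snp_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(A = A, B = B), rowRanges = rr,
    colData = S4Vectors::DataFrame(pool_id = arrays, group = groups,
                                   row.names = arrays))
  new("PoolIntensityExperiment", se)
}

#' Default run configuration
#'
#' All pipeline parameters in one nested list: cohort spec, pool design,
#' noise model, scan thresholds (genome-wide 5e-8, support 1e-5, 150 kb
#' locus window, 80% minimum specificity) and the dialect switches for
#' choices the study leaves open (MAPD mode, Yates correction, carrier semantics,
#' DQ2.2 combination rule). Saved/loaded as YAML by [readRunConfig()].
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_cases = 473L, n_controls = 714L, n_family = 357L,
                  msh5_maf_cases = 0.318, msh5_maf_controls = 0.071,
                  msh5_maf_family = 0.19, dqa1_r2 = 0.5),
    pools = list(n_case_pools = 9L, n_control_pools = 6L,
                 size_min = 33L, size_max = 44L),
    noise = list(ras_noise_sd = 0.03, array_bias_sd = 0.01),
    scan = list(n_null_snps = 2000L, gw_threshold = 5e-8,
                support_threshold = 1e-5, locus_window = 150000L,
                planted_frac_case = 0.45, planted_frac_control = 0.20),
    thresholds = list(min_specificity = 0.80),
    dialects = list(mapd_mode = "consecutive", yates = FALSE,
                    carrier = "atLeastOne", dq22_rule = "min")
  )
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [defaultRunConfig()] values; absent
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  config <- defaultRunConfig(user$seed %||% 1L)
  for (section in intersect(names(user), names(config))) {
    if (is.list(config[[section]])) {
      for (k in intersect(names(user[[section]]), names(config[[section]]))) {
        config[[section]][[k]] <- user[[section]][[k]]
      }
    } else {
      config[[section]] <- user[[section]]
    }
  }
  config
}

#' Run the full synthetic study pipeline
#'
#' Executes simulate -> pool -> allelotyping scan -> HLA calling ->
#' association -> classification, writing every intermediate as TSV plus a
#' machine-readable `summary.yaml` (headline statistics) and `log.txt`
#' (seeds, dialects, package version) into `outDir`. Re-running with the
#' same configuration is bit-identical.
#'
#' @param config nested list from [defaultRunConfig()] / [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @return list with the main results (`cohort`, `scan`, `hits`,
#'   `association`, `classification`, `summary`), invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dialects <- config$dialects
  panel <- defaultSnpPanel()

  ## 1. cohort
  spec <- cohortSpec(
    nCases = config$cohort$n_cases, nControls = config$cohort$n_controls,
    nFamily = config$cohort$n_family,
    msh5MafCases = config$cohort$msh5_maf_cases,
    msh5MafControls = config$cohort$msh5_maf_controls,
    msh5MafFamily = config$cohort$msh5_maf_family,
    dqa1R2 = config$cohort$dqa1_r2,
    seed = deriveSeed(config$seed, 101))
  cohort <- generateCohort(spec)
  writeGenotypesTsv(cohort, file.path(outDir, "genotypes.tsv"))
  writeGenotypesVcf(cohort, file.path(outDir, "genotypes.vcf"), panel)

  ## 2. pools + pooled scan (planted effects at the two GWAS hits)
  if (config$pools$n_case_pools <= 0L || config$pools$n_control_pools <= 0L) {
    stopf("pool stage: need at least one case pool and one control pool")
  }
  design <- assignPools(cohort, config$pools$n_case_pools,
                        config$pools$n_control_pools,
                        c(config$pools$size_min, config$pools$size_max),
                        seed = deriveSeed(config$seed, 202))
  noise <- arrayNoiseModel(config$noise$ras_noise_sd,
                           config$noise$array_bias_sd,
                           seed = deriveSeed(config$seed, 303))
  planted <- data.frame(
    snp_id = c("rs9272346", "rs3130484"), chrom = "6",
    pos = c(32604372L, 31715882L),
    frac_case = config$scan$planted_frac_case,
    frac_control = config$scan$planted_frac_control)
  pie <- simulateScanPools(
    nNull = config$scan$n_null_snps, planted = planted,
    nCasePools = config$pools$n_case_pools,
    nControlPools = config$pools$n_control_pools, noise = noise,
    seed = deriveSeed(config$seed, 404))
  writePoolIntensities(pie, file.path(outDir, "pool_intensities.tsv"))
  scan <- allelotypeScan(pie, mapdMode = dialects$mapd_mode)
  write.table(scan$table, file.path(outDir, "scan_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- selectHits(scan$complete, config$scan$gw_threshold,
                     config$scan$support_threshold, config$scan$locus_window)
  write.table(hits$hits, file.path(outDir, "hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(manhattanTable(scan$complete),
              file.path(outDir, "manhattan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(qqTable(scan$complete), file.path(outDir, "qq.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 3. HLA calling + classification inputs
  called <- callCohortDiplotypes(cohort, dq22Rule = dialects$dq22_rule)
  writeGenotypesTsv(called, file.path(outDir, "diplotypes.tsv"))

  ## 4. association statistics
  assoc <- list(
    cd_msh5 = replicationContrast(called, "CD", "control", "rs3130484",
                                  yates = dialects$yates),
    cd_dqa1 = replicationContrast(called, "CD", "control", "rs9272346",
                                  yates = dialects$yates),
    family_msh5 = replicationContrast(called, "family", "control",
                                      "rs3130484", yates = dialects$yates),
    family_dqa1 = replicationContrast(called, "family", "control",
                                      "rs9272346", yates = dialects$yates),
    interaction_dominant = interactionTest(called, "dominant"),
    interaction_recessive = interactionTest(called, "recessive")
  )
  assocTab <- do.call(rbind, lapply(
    c("cd_msh5", "cd_dqa1", "family_msh5", "family_dqa1"), function(k) {
      a <- assoc[[k]]
      data.frame(contrast = k, p_genotype = a$genotype$p,
                 p_allele = a$allele$p, or = a$or$or,
                 ci_low = a$or$ciLow, ci_high = a$or$ciHigh)
    }))
  write.table(assocTab, file.path(outDir, "association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 5. classification
  rules <- list(ruleHlaOnly(), ruleHlaOrMsh5(dialects$carrier),
                ruleMsh5AndDqa1(dialects$carrier))
  search <- searchBestRule(rules, called,
                           minSpecificity = config$thresholds$min_specificity)
  write.table(search$audit, file.path(outDir, "classifiers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_gw_hits = nrow(hits$hits),
    gw_hits = hits$hits$snp,
    removed_array = scan$removed_array,
    association = stats::setNames(
      lapply(c("cd_msh5", "cd_dqa1", "family_msh5", "family_dqa1"),
             function(k) list(or = assoc[[k]]$or$or,
                              p_allele = assoc[[k]]$allele$p)),
      c("cd_msh5", "cd_dqa1", "family_msh5", "family_dqa1")),
    interaction_p = list(
      dominant = unname(waldP(assoc$interaction_dominant)["msh5:hla"]),
      recessive = unname(waldP(assoc$interaction_recessive)["msh5:hla"])),
    rules = stats::setNames(lapply(seq_len(nrow(search$audit)), function(i) {
      list(sensitivity_pct = search$audit$sensitivity_pct[i],
           specificity_pct = search$audit$specificity_pct[i])
    }), search$audit$rule),
    best_rule = if (is.null(search$best)) NULL else search$best@rule
  )
  yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
  writeLines(c(
    paste("cdscan version:", as.character(utils::packageVersion("cdscan"))),
    paste("master seed:", config$seed),
    paste("dialects:", paste(names(dialects), unlist(dialects),
                             sep = "=", collapse = ", ")),
    paste("removed control array (high MAPD):", scan$removed_array)
  ), file.path(outDir, "log.txt"))

  invisible(list(cohort = called, design = design, scan = scan, hits = hits,
                 association = assoc, classification = search,
                 summary = summary, outDir = outDir))
}
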