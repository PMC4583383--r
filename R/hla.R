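#' @include AllClasses.R
NULL

## tag SNPs per haplotype: DQ2.5 <- rs2187668; DQ8 <- rs7454108;
## DQ2.2 <- rs7775228 AND rs2395182 (both required on the haplotype)
tagSnpMap <- function() {
  list("DQ2.5" = "rs2187668", "DQ8" = "rs7454108",
       "DQ2.2" = c("rs7775228", "rs2395182"))
}

checkDosage <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% 0:2)) {
    stopf("%s dosages must be 0, 1 or 2 (missing data must be resolved first)",
          what)
  }
}

#' Call HLA-DQ haplotype dosages from the four tag SNPs
#'
#' DQ2.5 dosage is the rs2187668 dosage, DQ8 the rs7454108 dosage, and DQ2.2
#' the minimum of its two tag dosages (rs7775228, rs2395182) — both tags sit
#' on the DQ2.2 haplotype, so without phase the minimum is the conservative
#' bound on the number of haplotype copies. A `"max"` dialect is available.
#'
#' @param dosages named numeric/integer vector (or single-row data.frame) of
#'   minor-allele dosages; must contain all four tag SNPs with values in
#'   0/1/2. Extra entries are ignored.
#' @param dq22Rule `"min"` (default) or `"max"`: how the two DQ2.2 tag
#'   dosages combine.
#' @return named integer vector with elements `DQ2.5`, `DQ8`, `DQ2.2`.
#' @examples
#' callHaplotypeDosages(c(rs2187668 = 2, rs7454108 = 0,
#'                        rs7775228 = 0, rs2395182 = 0))
#' @export
callHaplotypeDosages <- function(dosages, dq22Rule = c("min", "max")) {
  dq22Rule <- match.arg(dq22Rule)
  if (is.data.frame(dosages)) dosages <- unlist(dosages[1, ])
  tags <- tagSnpMap()
  needed <- unlist(tags, use.names = FALSE)
  missing <- setdiff(needed, names(dosages))
  if (length(missing)) {
    stopf("missing tag SNP(s): %s", paste(missing, collapse = ", "))
  }
  d <- dosages[needed]
  checkDosage(d, "tag SNP")
  comb <- if (dq22Rule == "min") min else max
  c("DQ2.5" = as.integer(d[["rs2187668"]]),
    "DQ8"   = as.integer(d[["rs7454108"]]),
    "DQ2.2" = as.integer(comb(d[["rs7775228"]], d[["rs2395182"]])))
}

#' Call the DQ diplotype category from haplotype dosages
#'
#' Copies are taken greedily in the priority order DQ2.5 > DQ8 > DQ2.2 and
#' capped at two total: a dosage-2 haplotype forces the homozygous category,
#' two distinct dosage>=1 haplotypes give the heterozygous pairing, and a
#' single typed copy (the other chromosome carrying no typed haplotype) or no
#' copies at all yields `OTHER`. The fully contradictory input with all three
#' haplotypes at dosage 2 is rejected.
#'
#' @param hapDosages named vector with `DQ2.5`, `DQ8`, `DQ2.2` in 0/1/2, as
#'   from [callHaplotypeDosages()].
#' @return one of [dqCategories()].
#' @examples
#' callDiplotype(c(DQ2.5 = 1, DQ8 = 1, DQ2.2 = 0))  # "DQ2.5/DQ8"
#' @export
callDiplotype <- function(hapDosages) {
  haps <- c("DQ2.5", "DQ8", "DQ2.2")
  if (!all(haps %in% names(hapDosages))) {
    stopf("haplotype dosages must be named DQ2.5, DQ8, DQ2.2")
  }
  d <- hapDosages[haps]
  checkDosage(d, "haplotype")
  if (all(d == 2L)) {
    stopf("ambiguous input: DQ2.5, DQ8 and DQ2.2 all at dosage 2 imply more than two haplotype copies")
  }
  copies <- integer(3); remaining <- 2L
  for (i in seq_along(haps)) {            # greedy by priority, capped at 2
    copies[i] <- min(d[[i]], remaining)
    remaining <- remaining - copies[i]
  }
  names(copies) <- haps
  if (sum(copies) < 2L) return("OTHER")
  if (copies[["DQ2.5"]] == 2L) return("DQ2.5/DQ2.5")
  if (copies[["DQ8"]] == 2L) return("DQ8/DQ8")
  if (copies[["DQ2.2"]] == 2L) return("DQ2.2/DQ2.2")
  pair <- haps[copies == 1L]
  paste(pair, collapse = "/")             # priority order gives the label
}

#' Label a diplotype as an HLA risk genotype
#'
#' Risk-positive iff the category is one of the three DQ2.5-containing
#' genotypes (DQ2.5/DQ2.5, DQ2.5/DQ2.2, DQ2.5/DQ8).
#'
#' @param diplotype character vector of categories from [dqCategories()].
#' @return logical vector.
#' @export
labelRisk <- function(diplotype) {
  bad <- setdiff(unique(diplotype), dqCategories())
  if (length(bad)) stopf("unknown diplotype category: %s",
                         paste(bad, collapse = ", "))
  diplotype %in% hlaRiskCategories()
}

#' Call diplotypes and risk labels for a whole genotype table
#'
#' Vectorised driver over [callHaplotypeDosages()] and [callDiplotype()]:
#' appends `DQ2.5`, `DQ8`, `DQ2.2` haplotype dosages, the `diplotype`
#' category and the `is_risk` flag. Samples with missing tag dosages are
#' reported by id rather than silently dropped.
#'
#' @param table genotype table with the four tag-SNP dosage columns.
#' @param dq22Rule passed to [callHaplotypeDosages()].
#' @return the table with calling columns appended (any pre-existing
#'   `diplotype` column is overwritten by the called one).
#' @export
callCohortDiplotypes <- function(table, dq22Rule = c("min", "max")) {
  dq22Rule <- match.arg(dq22Rule)
  needed <- unlist(tagSnpMap(), use.names = FALSE)
  missing <- setdiff(needed, colnames(table))
  if (length(missing)) {
    stopf("genotype table lacks tag SNP column(s): %s",
          paste(missing, collapse = ", "))
  }
  incomplete <- !complete.cases(table[, needed])
  if (any(incomplete)) {
    stopf("missing tag dosages for sample(s): %s",
          paste(utils::head(table$sample_id[incomplete], 5), collapse = ", "))
  }
  comb <- if (dq22Rule == "min") pmin else pmax
  table$DQ2.5 <- as.integer(table$rs2187668)
  table$DQ8 <- as.integer(table$rs7454108)
  table$DQ2.2 <- as.integer(comb(table$rs7775228, table$rs2395182))
  table$diplotype <- vapply(seq_len(nrow(table)), function(i) {
    callDiplotype(c(DQ2.5 = table$DQ2.5[i], DQ8 = table$DQ8[i],
                    DQ2.2 = table$DQ2.2[i]))
  }, character(1))
  table$is_risk <- labelRisk(table$diplotype)
  table
}
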