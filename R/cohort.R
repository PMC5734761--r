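#' Pedigreed genotype cohort
#'
#' The central container of the pipeline: a set of samples with family
#' links, sex and affection status, plus a sample-by-marker genotype
#' matrix coded as the dosage of allele 1 (0, 1, 2; `NA` = missing call).
#' Missing genotypes are always `NA`, never a zero dosage, so allele
#' counts are unbiased by missingness.
#'
#' @param ped data.frame with columns `fid`, `iid`, `pid`, `mid`, `sex`,
#'   `aff`. PLINK conventions: `pid`/`mid` are `"0"` for unknown parents,
#'   `sex` is 1 = male / 2 = female, `aff` is 1 = unaffected / 2 =
#'   affected / 0 = unknown.
#' @param geno integer matrix, samples x markers, dosage of allele 1 in
#'   `{0, 1, 2, NA}`. Row names must equal `ped$iid`, column names
#'   `map$snp`.
#' @param map data.frame with columns `chr` (integer), `snp`, `pos`
#'   (1-based base pairs), `a1`, `a2` (single-character alleles).
#'
#' @return An object of class `pedigree_cohort`: a list with elements
#'   `ped`, `geno`, `map`.
#' @export
pedigree_cohort <- function(ped, geno, map) {
  req <- c("fid", "iid", "pid", "mid", "sex", "aff")
  if (!all(req %in% names(ped)))
    stop("ped must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(ped$iid))
    stop("sample IDs (iid) must be unique")
  if (!is.matrix(geno))
    stop("geno must be a matrix")
  if (nrow(geno) != nrow(ped))
    stop("geno has ", nrow(geno), " rows but ped has ", nrow(ped), " samples")
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " columns but map has ", nrow(map), " markers")
  if (anyDuplicated(map$snp))
    stop("marker IDs (map$snp) must be unique")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad))
    stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(geno) <- as.character(ped$iid)
  colnames(geno) <- as.character(map$snp)
  ped$fid <- as.character(ped$fid)
  ped$iid <- as.character(ped$iid)
  ped$pid <- as.character(ped$pid)
  ped$mid <- as.character(ped$mid)
  structure(list(ped = ped, geno = geno, map = map),
            class = "pedigree_cohort")
}

#' @export
print.pedigree_cohort <- function(x, ...) {
  cat("pedigree_cohort:", nrow(x$ped), "samples,", nrow(x$map), "markers\n")
  cat("  families:", length(unique(x$ped$fid)),
      " affected:", sum(x$ped$aff == 2),
      " unaffected:", sum(x$ped$aff == 1), "\n")
  cat("  missing call rate:",
      format(mean(is.na(x$geno)), digits = 3), "\n")
  invisible(x)
}

#' Number of samples / markers in a cohort
#' @param cohort a `pedigree_cohort`
#' @return integer count
#' @export
n_samples <- function(cohort) nrow(cohort$ped)

#' @rdname n_samples
#' @export
n_markers <- function(cohort) nrow(cohort$map)

#' Subset a cohort by samples and/or markers
#'
#' @param cohort a `pedigree_cohort`
#' @param samples character vector of sample IDs to keep (default all)
#' @param markers character vector of marker IDs to keep (default all)
#' @return a `pedigree_cohort`
#' @export
subset_cohort <- function(cohort, samples = NULL, markers = NULL) {
  keep_s <- if (is.null(samples)) cohort$ped$iid else as.character(samples)
  keep_m <- if (is.null(markers)) cohort$map$snp else as.character(markers)
  miss_s <- setdiff(keep_s, cohort$ped$iid)
  if (length(miss_s)) stop("unknown sample IDs: ", paste(head(miss_s), collapse = ", "))
  miss_m <- setdiff(keep_m, cohort$map$snp)
  if (length(miss_m)) stop("unknown marker IDs: ", paste(head(miss_m), collapse = ", "))
  si <- match(keep_s, cohort$ped$iid)
  mi <- match(keep_m, cohort$map$snp)
  ped <- cohort$ped[si, , drop = FALSE]
  # orphaned parent links are reset so pedigrees stay resolvable
  ped$pid[!(ped$pid %in% ped$iid)] <- "0"
  ped$mid[!(ped$mid %in% ped$iid)] <- "0"
  rownames(ped) <- NULL
  map <- cohort$map[mi, , drop = FALSE]
  rownames(map) <- NULL
  pedigree_cohort(ped, cohort$geno[si, mi, drop = FALSE], map)
}

#' Per-marker allele-1 frequencies in affected and unaffected samples
#'
#' Plain allele counting over all affected and all unaffected individuals
#' (relatives included), each computed on non-missing calls only. This is
#' the frequency computation the directed eQTL binning consumes.
#'
#' @param cohort a `pedigree_cohort`
#' @return data.frame with columns `snp`, `a1`, `a2`, `freq_a1_cases`,
#'   `freq_a1_controls` (NaN where a group has no non-missing call)
#' @export
snp_freq_table <- function(cohort) {
  case <- cohort$ped$aff == 2
  ctrl <- cohort$ped$aff == 1
  fr <- function(g) {
    n <- colSums(!is.na(g))
    cnt <- colSums(g, na.rm = TRUE)
    ifelse(n > 0, cnt / (2 * n), NaN)
  }
  data.frame(snp = cohort$map$snp, a1 = cohort$map$a1, a2 = cohort$map$a2,
             freq_a1_cases = fr(cohort$geno[case, , drop = FALSE]),
             freq_a1_controls = fr(cohort$geno[ctrl, , drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Case/control frequency of one allele at one SNP
#'
#' @param cohort a `pedigree_cohort`
#' @param snp marker ID
#' @param allele the allele whose frequency is wanted; must be one of the
#'   marker's two alleles
#' @return named numeric vector `c(cases =, controls =)`; NaN (with a
#'   warning) for a group with no non-missing genotype
#' @export
case_control_allele_freq <- function(cohort, snp, allele) {
  j <- match(snp, cohort$map$snp)
  if (is.na(j)) stop("SNP not present in cohort: ", snp)
  a1 <- cohort$map$a1[j]; a2 <- cohort$map$a2[j]
  if (!(allele %in% c(a1, a2)))
    stop("allele ", allele, " is not one of the alleles (", a1, "/", a2,
         ") of SNP ", snp)
  g <- cohort$geno[, j]
  if (allele == a2) g <- 2L - g
  out <- c(cases = NaN, controls = NaN)
  for (grp in c(cases = 2, controls = 1)) {
    gg <- g[cohort$ped$aff == grp]
    n <- sum(!is.na(gg))
    nm <- if (grp == 2) "cases" else "controls"
    if (n == 0) {
      warning("no non-missing genotypes for ", nm, " at SNP ", snp)
    } else {
      out[nm] <- sum(gg, na.rm = TRUE) / (2 * n)
    }
  }
  out
}
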