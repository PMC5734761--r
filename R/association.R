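#' Family-aware stratified CMH association scan (DFAM-style)
#'
#' For each marker, observed-minus-expected allele-1 counts in affected
#' individuals are accumulated over three kinds of independent strata and
#' combined in a 1-df Cochran-Mantel-Haenszel chi-square:
#'
#' * TDT stratum: for each affected genotyped child with both parents
#'   genotyped, transmissions from heterozygous parents are Bernoulli(1/2)
#'   under the null. The joint allele-1 contribution of the het parents is
#'   the child dosage minus the transmissions forced by homozygous
#'   parents; O accumulates it, E adds n_het/2 and V adds n_het/4.
#'   Mendelian-inconsistent trio calls are excluded. With exactly one
#'   genotyped parent (duo), a heterozygous parent's transmission is
#'   resolvable only for a homozygous child and is counted then.
#' * Sibship strata: each family without two genotyped parents but with
#'   at least one affected and one unaffected genotyped sib contributes a
#'   within-family contrast: O = allele-1 count in affected sibs, E and V
#'   from the hypergeometric draw of the affected allele slots from the
#'   sibship's pooled allele counts.
#' * Unrelated stratum: singleton cases and controls form a single 2x2
#'   (case/control x allele) with hypergeometric E and V.
#'
#' The statistic is `T = (sum(O-E))^2 / sum(V)`, p from chi-square(1).
#' Markers with zero total variance are uninformative: p = 1, flagged.
#'
#' @param cohort a post-QC [pedigree_cohort()] with affection status
#' @return data.frame with one row per marker: `snp`, `chr`, `bp`, `a1`,
#'   `a2`, `p`, `obs`, `exp`, `var`, `stat`, `uninformative`
#' @export
dfam_scan <- function(cohort) {
  ped <- cohort$ped; G <- cohort$geno; map <- cohort$map
  m <- ncol(G)
  O <- numeric(m); E <- numeric(m); V <- numeric(m)

  fam_size <- table(ped$fid)
  in_family <- fam_size[ped$fid] > 1
  has_parent <- ped$pid %in% ped$iid | ped$mid %in% ped$iid

  # --- TDT contributions: affected children with >=1 genotyped parent
  kids <- which(has_parent & ped$aff == 2)
  for (i in kids) {
    fi <- match(ped$pid[i], ped$iid)
    mi <- match(ped$mid[i], ped$iid)
    gc <- G[i, ]
    if (!is.na(fi) && !is.na(mi)) {
      gf <- G[fi, ]; gm <- G[mi, ]
      valid <- !is.na(gc) & !is.na(gf) & !is.na(gm) &
        !.mendel_inconsistent(gc, gf, gm)
      nhet <- ((gf == 1) + (gm == 1)) * valid
      nhet[is.na(nhet)] <- 0
      forced <- (gf == 2) + (gm == 2)
      contrib <- ifelse(valid & nhet >= 1, gc - forced, 0)
      contrib[is.na(contrib)] <- 0
      O <- O + contrib
      E <- E + nhet / 2
      V <- V + nhet / 4
    } else {
      pi <- if (!is.na(fi)) fi else mi
      gp <- G[pi, ]
      # duo: het parent, homozygous child -> transmission resolved
      valid <- !is.na(gc) & !is.na(gp) & gp == 1 & gc != 1
      valid[is.na(valid)] <- FALSE
      O <- O + ifelse(valid, gc / 2, 0)
      E <- E + 0.5 * valid
      V <- V + 0.25 * valid
    }
  }

  # --- sibship strata: families lacking two genotyped parents
  for (f in names(fam_size)[fam_size > 1]) {
    rows <- which(ped$fid == f)
    kids_f <- rows[ped$pid[rows] != "0" | ped$mid[rows] != "0"]
    if (length(kids_f) < 2) next
    two_parents <- any(ped$pid[kids_f] %in% ped$iid) &&
      any(ped$mid[kids_f] %in% ped$iid)
    if (two_parents) next
    aff <- ped$aff[kids_f]
    if (!any(aff == 2) || !any(aff == 1)) next
    Gs <- G[kids_f, , drop = FALSE]
    nn_aff <- colSums(!is.na(Gs[aff == 2, , drop = FALSE]))
    nn_un <- colSums(!is.na(Gs[aff == 1, , drop = FALSE]))
    use <- nn_aff > 0 & nn_un > 0
    Ntot <- 2 * (nn_aff + nn_un)
    K <- colSums(Gs, na.rm = TRUE)
    na_all <- 2 * nn_aff
    Oa <- colSums(Gs[aff == 2, , drop = FALSE], na.rm = TRUE)
    p1 <- ifelse(Ntot > 0, K / Ntot, 0)
    Ee <- na_all * p1
    Vv <- ifelse(Ntot > 1,
                 na_all * p1 * (1 - p1) * (Ntot - na_all) / (Ntot - 1), 0)
    O <- O + ifelse(use, Oa, 0)
    E <- E + ifelse(use, Ee, 0)
    V <- V + ifelse(use, Vv, 0)
  }

  # --- unrelated stratum: singletons with known affection
  singles <- which(!in_family & !has_parent & ped$aff %in% c(1, 2))
  if (length(singles)) {
    aff <- ped$aff[singles]
    Gu <- G[singles, , drop = FALSE]
    if (any(aff == 2) && any(aff == 1)) {
      nn_ca <- colSums(!is.na(Gu[aff == 2, , drop = FALSE]))
      nn_co <- colSums(!is.na(Gu[aff == 1, , drop = FALSE]))
      use <- nn_ca > 0 & nn_co > 0
      Ntot <- 2 * (nn_ca + nn_co)
      K <- colSums(Gu, na.rm = TRUE)
      na_all <- 2 * nn_ca
      Oa <- colSums(Gu[aff == 2, , drop = FALSE], na.rm = TRUE)
      p1 <- ifelse(Ntot > 0, K / Ntot, 0)
      Ee <- na_all * p1
      Vv <- ifelse(Ntot > 1,
                   na_all * p1 * (1 - p1) * (Ntot - na_all) / (Ntot - 1), 0)
      O <- O + ifelse(use, Oa, 0)
      E <- E + ifelse(use, Ee, 0)
      V <- V + ifelse(use, Vv, 0)
    }
  }

  uninf <- V <= 0
  stat <- ifelse(uninf, 0, (O - E)^2 / ifelse(V > 0, V, 1))
  p <- ifelse(uninf, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(snp = map$snp, chr = map$chr, bp = map$pos, a1 = map$a1,
             a2 = map$a2, p = p, obs = O, exp = E, var = V, stat = stat,
             uninformative = uninf, stringsAsFactors = FALSE)
}

#' Single-marker DFAM test
#'
#' @param cohort a [pedigree_cohort()]
#' @param marker marker ID
#' @return one-row data.frame as in [dfam_scan()]
#' @export
dfam_test <- function(cohort, marker) {
  if (!marker %in% cohort$map$snp) stop("unknown marker: ", marker)
  res <- dfam_scan(subset_cohort(cohort, markers = marker))
  res
}

#' Manhattan-plot coordinates
#'
#' @param results association results with columns `snp`, `chr`, `bp`, `p`
#' @return data.frame `marker`, `chromosome`, `position`, `neglog10p`
#' @export
manhattan_coords <- function(results) {
  data.frame(marker = results$snp, chromosome = results$chr,
             position = results$bp, neglog10p = -log10(results$p),
             stringsAsFactors = FALSE)
}
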