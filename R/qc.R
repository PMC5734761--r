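#' Per-sample missing-call fraction
#'
#' @param cohort a [pedigree_cohort()]
#' @return named numeric vector (missing calls / total markers) per sample
#' @export
sample_missingness <- function(cohort) {
  if (n_markers(cohort) < 1) stop("cohort has no markers")
  rowMeans(is.na(cohort$geno))
}

#' Heterozygosity outlier filter
#'
#' Per-sample heterozygosity rate = heterozygous calls / non-missing
#' calls; samples whose rate is more than `k_sd` standard deviations from
#' the cohort mean (either direction) are removed.
#'
#' @param cohort a [pedigree_cohort()]
#' @param k_sd removal threshold in SD units (default 3)
#' @return list with `keep` (sample IDs retained) and `report`
#'   (data.frame iid, het_rate, z, removed)
#' @export
heterozygosity_filter <- function(cohort, k_sd = 3) {
  G <- cohort$geno
  nn <- rowSums(!is.na(G))
  if (sum(nn > 0) < 2) stop("need >= 2 samples with non-missing calls")
  het <- rowSums(G == 1, na.rm = TRUE) / pmax(nn, 1)
  s <- sd(het)
  if (s == 0 || !is.finite(s)) {
    warning("zero variance in heterozygosity rates; retaining all samples")
    z <- rep(0, length(het))
  } else {
    z <- (het - mean(het)) / s
  }
  removed <- abs(z) > k_sd
  list(keep = cohort$ped$iid[!removed],
       report = data.frame(iid = cohort$ped$iid, het_rate = het, z = z,
                           removed = removed, stringsAsFactors = FALSE))
}

#' Mendelian error counts
#'
#' A child call is an error when it is inconsistent with the available
#' parental genotypes: with both parents genotyped, the child dosage must
#' be expressible as a sum of one transmissible allele per parent; with
#' one genotyped parent (duo), the child must carry at least one allele
#' that parent can transmit. Each error increments the child, each
#' genotyped parent of that child, and the marker.
#'
#' @param cohort a [pedigree_cohort()]
#' @return list with `per_sample` (named integer vector over all samples)
#'   and `per_marker` (named integer vector over all markers)
#' @export
mendel_errors <- function(cohort) {
  ped <- cohort$ped; G <- cohort$geno
  # reject circular pedigrees (a sample its own ancestor)
  for (i in seq_len(nrow(ped))) {
    seen <- character(); cur <- ped$iid[i]
    while (TRUE) {
      j <- match(cur, ped$iid)
      if (is.na(j)) break
      nxt <- ped$pid[j]
      if (nxt == "0") break
      if (nxt %in% c(seen, ped$iid[i])) stop("circular pedigree at sample ", ped$iid[i])
      seen <- c(seen, cur); cur <- nxt
    }
  }
  per_sample <- setNames(integer(nrow(ped)), ped$iid)
  per_marker <- setNames(integer(n_markers(cohort)), cohort$map$snp)
  for (i in seq_len(nrow(ped))) {
    pid <- ped$pid[i]; mid <- ped$mid[i]
    fi <- match(pid, ped$iid); mi <- match(mid, ped$iid)
    if (is.na(fi) && is.na(mi)) next
    gc <- G[i, ]
    gf <- if (!is.na(fi)) G[fi, ] else rep(NA_integer_, ncol(G))
    gm <- if (!is.na(mi)) G[mi, ] else rep(NA_integer_, ncol(G))
    err <- .mendel_inconsistent(gc, gf, gm)
    ne <- sum(err)
    if (ne == 0) next
    per_sample[i] <- per_sample[i] + ne
    if (!is.na(fi) && any(err & !is.na(gf)))
      per_sample[fi] <- per_sample[fi] + sum(err & !is.na(gf))
    if (!is.na(mi) && any(err & !is.na(gm)))
      per_sample[mi] <- per_sample[mi] + sum(err & !is.na(gm))
    per_marker[err] <- per_marker[err] + 1L
  }
  list(per_sample = per_sample, per_marker = per_marker)
}

# vectorized Mendel consistency over markers: TRUE where the child call
# is impossible given the (possibly missing) parental calls
.mendel_inconsistent <- function(gc, gf, gm) {
  # transmissible-set bounds per parent: lo/hi of the allele-1 dosage a
  # parent can pass (NA parent passes 0 or 1)
  lo <- function(g) ifelse(is.na(g), 0L, ifelse(g == 2, 1L, 0L))
  hi <- function(g) ifelse(is.na(g), 1L, ifelse(g == 0, 0L, 1L))
  bad <- !is.na(gc) & (gc < lo(gf) + lo(gm) | gc > hi(gf) + hi(gm))
  bad & !(is.na(gf) & is.na(gm))
}

#' Per-marker QC summary and filter
#'
#' A marker is removed iff its missing fraction exceeds `miss_max`
#' (strict), its Mendelian error count exceeds `mendel_max` (strict), or
#' it is monomorphic (MAF = 0, computed on non-missing calls).
#'
#' @param cohort a [pedigree_cohort()]
#' @param miss_max missing-fraction threshold (default 0.02)
#' @param mendel_max Mendelian-error-count threshold (default 3)
#' @return list with `keep` (marker IDs retained) and `report`
#'   (data.frame snp, miss, mendel, maf, removed)
#' @export
marker_filters <- function(cohort, miss_max = 0.02, mendel_max = 3) {
  G <- cohort$geno
  miss <- colMeans(is.na(G))
  mend <- mendel_errors(cohort)$per_marker
  maf <- marker_maf(cohort)
  removed <- miss > miss_max | mend > mendel_max | maf == 0
  list(keep = cohort$map$snp[!removed],
       report = data.frame(snp = cohort$map$snp, miss = miss,
                           mendel = as.integer(mend), maf = maf,
                           removed = removed, stringsAsFactors = FALSE))
}

#' Minor allele frequency per marker (non-missing calls only)
#' @param cohort a [pedigree_cohort()]
#' @return named numeric vector in [0, 0.5]; NaN for fully missing markers
#' @export
marker_maf <- function(cohort) {
  G <- cohort$geno
  n <- colSums(!is.na(G))
  f <- ifelse(n > 0, colSums(G, na.rm = TRUE) / (2 * n), NaN)
  setNames(pmin(f, 1 - f), cohort$map$snp)
}

#' Pairwise genotype-dosage r-squared
#'
#' Squared Pearson correlation of dosage vectors, computed on pairwise
#' complete observations.
#'
#' @param g1,g2 dosage vectors
#' @return r-squared (0 when either vector is constant)
#' @export
dosage_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(0)
  if (sd(g1[ok]) == 0 || sd(g2[ok]) == 0) return(0)
  cor(g1[ok], g2[ok])^2
}

#' Windowed greedy LD pruning
#'
#' Within each sliding window of `window` markers (slid by `step`),
#' repeatedly drops one marker of any pair with r-squared >= `r2_max`
#' until no within-window pair violates; of a violating pair the marker
#' with the lower MAF is dropped (tie: the later position). Markers are
#' processed in map order (chromosome, position); cross-chromosome pairs
#' are never compared.
#'
#' @param cohort a [pedigree_cohort()]
#' @param r2_max prune threshold (default 0.2: retained set has all
#'   pairwise r-squared below this)
#' @param window window size in markers (default 50)
#' @param step slide in markers (default 5)
#' @return character vector of retained marker IDs, in map order
#' @export
ld_prune <- function(cohort, r2_max = 0.2, window = 50, step = 5) {
  map <- cohort$map
  ord <- order(map$chr, map$pos)
  G <- cohort$geno[, ord, drop = FALSE]
  snp <- map$snp[ord]; chr <- map$chr[ord]
  maf <- marker_maf(cohort)[snp]
  m <- length(snp)
  removed <- rep(FALSE, m)
  starts <- unique(c(seq(1, max(1, m - window + 1), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    repeat {
      act <- idx[!removed[idx]]
      if (length(act) < 2) break
      R2 <- suppressWarnings(cor(G[, act, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      R2[is.na(R2)] <- 0
      same_chr <- outer(chr[act], chr[act], "==")
      R2[!same_chr] <- 0
      diag(R2) <- 0
      viol <- which(R2 >= r2_max, arr.ind = TRUE)
      if (nrow(viol) == 0) break
      v <- viol[1, ]
      i1 <- act[v[1]]; i2 <- act[v[2]]
      drop <- if (maf[i1] < maf[i2]) i1
              else if (maf[i2] < maf[i1]) i2
              else max(i1, i2)  # tie: later position
      removed[drop] <- TRUE
    }
  }
  snp[!removed]
}

#' Genomic relationship matrix from standardized dosages
#'
#' GRM entry (i, j) = mean over markers of `z_i z_j`, with
#' `z = (g - 2 f) / sqrt(2 f (1 - f))` and `f` the pooled allele-1
#' frequency on non-missing calls. Missing dosages are mean-imputed
#' (z = 0). Monomorphic markers are skipped with a warning.
#'
#' @param geno dosage matrix, samples x markers
#' @return symmetric n x n matrix with sample row names
#' @export
grm_matrix <- function(geno) {
  n <- colSums(!is.na(geno))
  f <- colSums(geno, na.rm = TRUE) / (2 * pmax(n, 1))
  poly <- f > 0 & f < 1 & n > 0
  if (!all(poly))
    warning(sum(!poly), " monomorphic or fully-missing marker(s) skipped in GRM")
  if (!any(poly)) stop("no polymorphic markers for GRM")
  Z <- sweep(geno[, poly, drop = FALSE], 2, 2 * f[poly], "-")
  Z <- sweep(Z, 2, sqrt(2 * f[poly] * (1 - f[poly])), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / sum(poly)
  (K + t(K)) / 2
}

#' PCA ancestry-outlier filter against a reference panel
#'
#' Study and reference samples are pooled; a GRM is built from the shared
#' (ideally LD-pruned) markers and its first `n_components` eigenvectors
#' give per-sample scores. The ancestry distance E of each study sample
#' is the Euclidean distance of its score vector to the mean score of the
#' reference samples; study samples with `E > k_sd * SD(E)` (SD over all
#' study samples, single pass) are removed.
#'
#' @param cohort the study [pedigree_cohort()]
#' @param reference the reference [pedigree_cohort()] (e.g. a simulated
#'   homogeneous panel standing in for a reference population)
#' @param k_sd removal threshold in SD-of-E units (default 5)
#' @param n_components number of leading eigenvectors used (default 3)
#' @param markers optional marker IDs (e.g. from [ld_prune()]); default
#'   all shared markers
#' @return list with `keep` (study sample IDs retained) and `report`
#'   (data.frame iid, E, removed), plus `scores` for inspection
#' @export
ancestry_outlier_filter <- function(cohort, reference, k_sd = 5,
                                    n_components = 3, markers = NULL) {
  shared <- intersect(cohort$map$snp, reference$map$snp)
  if (!is.null(markers)) shared <- intersect(shared, markers)
  if (length(shared) == 0) stop("no shared markers between study and reference")
  Gs <- cohort$geno[, shared, drop = FALSE]
  Gr <- reference$geno[, shared, drop = FALSE]
  # align reference dosage orientation to the study's allele 1
  sa <- cohort$map$a1[match(shared, cohort$map$snp)]
  ra <- reference$map$a1[match(shared, reference$map$snp)]
  flip <- sa != ra
  Gr[, flip] <- 2L - Gr[, flip]
  X <- rbind(Gs, Gr)
  K <- grm_matrix(X)
  eig <- eigen(K, symmetric = TRUE)
  sc <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(n_components)], 0)), n_components)
  ns <- nrow(Gs)
  ref_centroid <- colMeans(sc[-(seq_len(ns)), , drop = FALSE])
  E <- sqrt(rowSums(sweep(sc[seq_len(ns), , drop = FALSE], 2,
                          ref_centroid, "-")^2))
  sdE <- sd(E)
  removed <- if (sdE > 0) E > k_sd * sdE else rep(FALSE, ns)
  list(keep = cohort$ped$iid[!removed],
       report = data.frame(iid = cohort$ped$iid, E = E, removed = removed,
                           stringsAsFactors = FALSE),
       scores = sc)
}

#' Run the full QC chain
#'
#' Filter order: sample filters first (missingness > `miss_max`,
#' heterozygosity beyond `het_k_sd` SD, Mendelian errors >
#' `sample_mendel_max`), then marker filters (missingness, Mendelian
#' errors, monomorphic), then LD pruning and — when a reference panel is
#' supplied — PCA ancestry-outlier removal on the pruned set.
#'
#' @param cohort a [pedigree_cohort()]
#' @param reference optional reference panel for the ancestry filter
#' @param miss_max per-sample and per-marker missingness threshold (0.02)
#' @param het_k_sd heterozygosity threshold in SD (3)
#' @param sample_mendel_max per-sample Mendelian error threshold (100)
#' @param marker_mendel_max per-marker Mendelian error threshold (3)
#' @param r2_max,window,step LD pruning parameters
#' @param ancestry_k_sd ancestry threshold in SD-of-E units (5)
#' @return list with the post-QC `cohort`, the `pruned` marker IDs, and a
#'   `report` list from each stage
#' @export
run_qc <- function(cohort, reference = NULL, miss_max = 0.02, het_k_sd = 3,
                   sample_mendel_max = 100, marker_mendel_max = 3,
                   r2_max = 0.2, window = 50, step = 5, ancestry_k_sd = 5) {
  rep <- list()
  miss <- sample_missingness(cohort)
  keep <- cohort$ped$iid[miss <= miss_max]
  rep$sample_missingness <- data.frame(iid = cohort$ped$iid, miss = miss,
                                       removed = miss > miss_max)
  co <- subset_cohort(cohort, samples = keep)
  het <- heterozygosity_filter(co, k_sd = het_k_sd)
  rep$heterozygosity <- het$report
  co <- subset_cohort(co, samples = het$keep)
  me <- mendel_errors(co)
  keep <- names(me$per_sample)[me$per_sample <= sample_mendel_max]
  rep$sample_mendel <- data.frame(iid = names(me$per_sample),
                                  mendel = as.integer(me$per_sample),
                                  removed = me$per_sample > sample_mendel_max)
  co <- subset_cohort(co, samples = keep)
  mf <- marker_filters(co, miss_max = miss_max, mendel_max = marker_mendel_max)
  rep$markers <- mf$report
  co <- subset_cohort(co, markers = mf$keep)
  pruned <- ld_prune(co, r2_max = r2_max, window = window, step = step)
  rep$pruned_count <- length(pruned)
  if (!is.null(reference)) {
    anc <- ancestry_outlier_filter(co, reference, k_sd = ancestry_k_sd,
                                   markers = pruned)
    rep$ancestry <- anc$report
    co <- subset_cohort(co, samples = anc$keep)
  }
  list(cohort = co, pruned = pruned, report = rep)
}
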