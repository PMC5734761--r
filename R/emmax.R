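#' Kinship matrix from post-QC genotypes
#'
#' Standardized-dosage genomic relationship matrix (same construction as
#' the QC GRM); missing dosages are mean-imputed per marker and
#' monomorphic markers skipped with a warning.
#'
#' @param cohort a [pedigree_cohort()]
#' @return symmetric matrix over samples, class `kinship_matrix`
#' @export
kinship_matrix <- function(cohort) {
  K <- grm_matrix(cohort$geno)
  rownames(K) <- colnames(K) <- cohort$ped$iid
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Fit the mixed-model null (variance components)
#'
#' REML fit of `y = mu + g + e`, `Var(y) = sigma_g^2 K + sigma_e^2 I`,
#' with the binary phenotype treated as quantitative. The kinship matrix
#' is spectrally decomposed once and the restricted likelihood profiled
#' over the single variance ratio `delta = sigma_e^2 / sigma_g^2` by
#' one-dimensional optimization on the eigenbasis. Both components are
#' non-negative by construction.
#'
#' @param phenotype numeric vector (0/1 coding for case status)
#' @param kinship square symmetric kinship matrix over the same samples
#' @return list with `sigma_g2`, `sigma_e2`, `delta`, `h2`
#'   (= sigma_g2 / (sigma_g2 + sigma_e2)), and the rotation (`U`,
#'   `eigenvalues`) reused by [emmax_scan()]
#' @export
emmax_fit_null <- function(phenotype, kinship) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (nrow(kinship) != n) stop("kinship dimension does not match phenotype")
  if (max(abs(kinship - t(kinship))) > 1e-12) stop("kinship must be symmetric")
  if (var(y) == 0) stop("phenotype is constant; variance components undefined")
  eig <- eigen(kinship, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8 * max(abs(lam)))
    stop("kinship matrix is not positive semi-definite")
  lam <- pmax(lam, 0) + 1e-8  # jitter keeps weights finite at delta -> 0
  U <- eig$vectors
  yr <- crossprod(U, y)
  xr <- crossprod(U, rep(1, n))
  reml <- function(logdelta) {
    d <- exp(logdelta)
    w <- lam + d
    bx <- sum(xr^2 / w)
    beta <- sum(xr * yr / w) / bx
    r <- yr - xr * beta
    s2 <- sum(r^2 / w) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(w)) + log(bx) + (n - 1))
  }
  opt <- optimize(reml, c(-15, 15), maximum = TRUE, tol = 1e-8)
  d <- exp(opt$maximum)
  w <- lam + d
  bx <- sum(xr^2 / w)
  beta <- sum(xr * yr / w) / bx
  s2g <- sum((yr - xr * beta)^2 / w) / (n - 1)
  list(sigma_g2 = s2g, sigma_e2 = d * s2g, delta = d,
       h2 = 1 / (1 + d), U = U, eigenvalues = lam,
       logREML = opt$objective)
}

#' Mixed-model association scan over three inheritance codings
#'
#' For each marker and each coding of the allele-1 dosage — additive
#' (0,1,2), dominant (0,1,1) and recessive (0,0,1) — a generalized
#' least-squares fit on the eigen-rotated data gives an effect estimate
#' and a Wald p-value; the smallest of the three p-values is reported
#' together with its effect size and model label (the multiplicity of
#' this min-p convention is deliberately not adjusted for, matching
#' common practice for model-agnostic scans; see package vignette).
#' Missing genotypes are mean-imputed per coding; a coding constant
#' across samples is skipped, and a marker with all codings skipped gets
#' p = 1, flagged.
#'
#' @param cohort a post-QC [pedigree_cohort()]
#' @param kinship a [kinship_matrix()] over the cohort samples
#' @param null_fit result of [emmax_fit_null()] (fitted once; if NULL it
#'   is fitted here)
#' @return data.frame per marker: `snp`, `chr`, `bp`, `a1`, `a2`, `p`,
#'   `beta`, `model` ("ADD"/"DOM"/"REC"), `uninformative`
#' @export
emmax_scan <- function(cohort, kinship = NULL, null_fit = NULL) {
  y <- cohort$ped$aff - 1
  if (is.null(kinship)) kinship <- kinship_matrix(cohort)
  if (is.null(null_fit)) null_fit <- emmax_fit_null(y, kinship)
  U <- null_fit$U
  w <- 1 / (null_fit$eigenvalues + null_fit$delta)
  n <- length(y)
  yr <- as.numeric(crossprod(U, y))
  or <- as.numeric(crossprod(U, rep(1, n)))
  S1 <- sum(w * or^2)
  Sy <- sum(w * or * yr)
  Syy <- sum(w * yr^2)

  G <- cohort$geno
  codings <- list(
    ADD = function(g) g + 0,
    DOM = function(g) (g >= 1) + 0,
    REC = function(g) (g == 2) + 0)
  m <- ncol(G)
  best_p <- rep(Inf, m); best_beta <- rep(NA_real_, m)
  best_model <- rep(NA_character_, m)
  for (lab in names(codings)) {
    X <- codings[[lab]](G)
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X))
    if (length(nas)) X[nas] <- mu[((nas - 1) %/% n) + 1]
    const <- apply(X, 2, function(v) max(v) - min(v)) == 0
    Xr <- crossprod(U, X)
    Sx <- colSums(w * or * Xr)
    Sxx <- colSums(w * Xr^2)
    Sxy <- colSums(w * yr * Xr)
    det <- S1 * Sxx - Sx^2
    ok <- !const & det > 1e-10 * S1 * pmax(Sxx, 1e-30)
    beta <- (S1 * Sxy - Sx * Sy) / det
    alpha <- (Sy - Sx * beta) / S1
    rss <- Syy - alpha * Sy - beta * Sxy
    sigma2 <- rss / (n - 2)
    se <- sqrt(pmax(sigma2 * S1 / det, 0))
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df = n - 2)
    p[!ok] <- Inf
    upd <- p < best_p
    best_p[upd] <- p[upd]
    best_beta[upd] <- beta[upd]
    best_model[upd] <- lab
  }
  uninf <- !is.finite(best_p)
  best_p[uninf] <- 1
  best_beta[uninf] <- NA_real_
  data.frame(snp = cohort$map$snp, chr = cohort$map$chr,
             bp = cohort$map$pos, a1 = cohort$map$a1, a2 = cohort$map$a2,
             p = pmax(best_p, .Machine$double.xmin), beta = best_beta,
             model = best_model, uninformative = uninf,
             stringsAsFactors = FALSE)
}
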