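# Hand-built cohorts and independent oracles shared across the suite.

# a cohort of nuclear families given per-family genotype/affection
# layout; `fams` is a list of lists with elements gf, gm, kids (matrix
# kids x markers), aff (vector over dad, mom, kids)
make_family_cohort <- function(fams, singles = NULL, chr = NULL, pos = NULL) {
  ped <- list(); G <- list()
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    kid_g <- f$kids
    if (is.null(dim(kid_g))) kid_g <- matrix(kid_g, nrow = 1)
    nk <- nrow(kid_g)
    fid <- sprintf("F%02d", i)
    iid <- c(paste0(fid, "_dad"), paste0(fid, "_mom"),
             sprintf("%s_kid%d", fid, seq_len(nk)))
    ped[[i]] <- data.frame(fid = fid, iid = iid,
                           pid = c("0", "0", rep(iid[1], nk)),
                           mid = c("0", "0", rep(iid[2], nk)),
                           sex = c(1L, 2L, rep(1L, nk)), aff = f$aff,
                           stringsAsFactors = FALSE)
    G[[i]] <- rbind(f$gf, f$gm, kid_g)
  }
  if (!is.null(singles)) {
    sg <- singles$geno
    if (is.null(dim(sg))) sg <- matrix(sg, nrow = 1)
    iid <- sprintf("S%02d", seq_len(nrow(sg)))
    ped[[length(ped) + 1]] <- data.frame(fid = iid, iid = iid, pid = "0",
                                         mid = "0", sex = 1L,
                                         aff = singles$aff,
                                         stringsAsFactors = FALSE)
    G[[length(G) + 1]] <- sg
  }
  ped <- do.call(rbind, ped)
  G <- do.call(rbind, G)
  m <- ncol(G)
  map <- data.frame(chr = if (is.null(chr)) rep(1L, m) else chr,
                    snp = sprintf("m%03d", seq_len(m)), cm = 0,
                    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  pedigree_cohort(ped, G, map)
}

# sibs-only family (parents listed in the pedigree but not genotyped /
# absent): a family of siblings sharing phantom parent IDs
make_sibship_cohort <- function(sib_geno, sib_aff, singles = NULL) {
  sg <- sib_geno
  if (is.null(dim(sg))) sg <- matrix(sg, nrow = 1)
  nk <- nrow(sg)
  iid <- sprintf("F01_kid%d", seq_len(nk))
  ped <- data.frame(fid = "F01", iid = iid, pid = "F01_dad",
                    mid = "F01_mom", sex = 1L, aff = sib_aff,
                    stringsAsFactors = FALSE)
  G <- sg
  if (!is.null(singles)) {
    s2 <- singles$geno
    if (is.null(dim(s2))) s2 <- matrix(s2, nrow = 1)
    iid2 <- sprintf("S%02d", seq_len(nrow(s2)))
    ped <- rbind(ped, data.frame(fid = iid2, iid = iid2, pid = "0",
                                 mid = "0", sex = 1L, aff = singles$aff,
                                 stringsAsFactors = FALSE))
    G <- rbind(G, s2)
  }
  m <- ncol(G)
  map <- data.frame(chr = 1L, snp = sprintf("m%03d", seq_len(m)), cm = 0,
                    pos = seq_len(m) * 1000L, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  pedigree_cohort(ped, G, map)
}

# --- independent oracles -------------------------------------------------

# brute-force Mendel consistency of one trio call (enumerates the
# transmissible alleles of each parent; NA parent transmits either)
oracle_mendel_consistent <- function(gc, gf, gm) {
  trans <- function(g) {
    if (is.na(g)) c(0L, 1L)
    else switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  }
  if (is.na(gc)) return(TRUE)
  if (is.na(gf) && is.na(gm)) return(TRUE)
  any(outer(trans(gf), trans(gm), "+") == gc)
}

# brute-force two-sided Fisher p by exhaustive hypergeometric
# enumeration from first principles (lchoose arithmetic, no dhyper)
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# brute-force Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# exhaustive enumeration of O's mean and variance when `na` allele
# slots are drawn without replacement from the 0/1 allele pool
oracle_allele_permutation <- function(alleles, na) {
  combos <- utils::combn(length(alleles), na)
  sums <- colSums(matrix(alleles[combos], nrow = na))
  c(E = mean(sums), V = mean(sums^2) - mean(sums)^2)
}
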