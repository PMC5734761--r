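#' Cohort simulation settings
#'
#' Defines a synthetic family-based case/control cohort: nuclear families
#' (two parents plus `children_per_family` children) ascertained on at
#' least one affected child, plus unrelated singleton cases and controls.
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium from
#' block-correlated haplotypes (first-order copying: within an LD block
#' the latent uniform of a marker is copied from its neighbour with
#' probability `within_block_r`, otherwise redrawn, which yields tunable
#' pairwise r-squared). Affection status follows a multiplicative
#' relative-risk penetrance model on the planted risk loci.
#'
#' Defaults emulate a cohort of a few hundred nuclear families recruited
#' through an affected index child together with unrelated cases and
#' controls, genotyped on a dense autosomal array: common variants
#' (MAF 0.05-0.5), moderately sized LD blocks, and a baseline prevalence
#' of 0.1 matching the elevated polyp prevalence seen among first-degree
#' relatives of patients.
#'
#' @param n_families number of nuclear families
#' @param children_per_family children per family (>= 1)
#' @param n_unrelated_cases,n_unrelated_controls singleton counts
#' @param n_markers number of autosomal markers
#' @param maf_range length-2 numeric in (0, 0.5]; per-marker allele-1
#'   frequencies are drawn uniformly from this range
#' @param ld_block_length markers per LD block
#' @param within_block_r haplotype copy probability in [0, 1]
#' @param risk_loci data.frame with columns `marker` (1-based marker
#'   index), `rr` (relative risk per model unit), `model` (one of
#'   "additive", "dominant", "recessive"); or NULL for a null cohort
#' @param baseline_prevalence penetrance of the zero-risk genotype, in (0,1)
#' @param n_chromosomes markers are split evenly over this many chromosomes
#' @param marker_spacing_bp base pairs between adjacent markers
#' @param seed integer seed; every generator is bit-reproducible given it
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_families = 300, children_per_family = 2,
                        n_unrelated_cases = 200, n_unrelated_controls = 200,
                        n_markers = 1000, maf_range = c(0.05, 0.5),
                        ld_block_length = 10, within_block_r = 0.8,
                        risk_loci = NULL, baseline_prevalence = 0.1,
                        n_chromosomes = 4, marker_spacing_bp = 5000,
                        seed = 1) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid cohort_spec field '", field, "': ", msg)
  chk(n_families >= 0, "n_families", "must be >= 0")
  chk(children_per_family >= 1, "children_per_family", "must be >= 1")
  chk(n_unrelated_cases >= 0, "n_unrelated_cases", "must be >= 0")
  chk(n_unrelated_controls >= 0, "n_unrelated_controls", "must be >= 0")
  chk(n_markers >= 1, "n_markers", "must be >= 1")
  chk(length(maf_range) == 2 && all(maf_range > 0) && all(maf_range <= 0.5)
      && maf_range[1] <= maf_range[2],
      "maf_range", "must be an ordered pair within (0, 0.5]")
  chk(ld_block_length >= 1, "ld_block_length", "must be >= 1")
  chk(within_block_r >= 0 && within_block_r <= 1,
      "within_block_r", "must be in [0, 1]")
  chk(baseline_prevalence > 0 && baseline_prevalence < 1,
      "baseline_prevalence", "must be in (0, 1)")
  if (!is.null(risk_loci)) {
    chk(is.data.frame(risk_loci) &&
          all(c("marker", "rr", "model") %in% names(risk_loci)),
        "risk_loci", "must be a data.frame with marker, rr, model")
    chk(all(risk_loci$marker >= 1 & risk_loci$marker <= n_markers),
        "risk_loci", "marker indices must be within 1..n_markers")
    chk(all(risk_loci$rr > 0), "risk_loci", "relative risks must be > 0")
    chk(all(risk_loci$model %in% c("additive", "dominant", "recessive")),
        "risk_loci", "model must be additive, dominant or recessive")
  }
  structure(list(n_families = n_families,
                 children_per_family = children_per_family,
                 n_unrelated_cases = n_unrelated_cases,
                 n_unrelated_controls = n_unrelated_controls,
                 n_markers = n_markers, maf_range = maf_range,
                 ld_block_length = ld_block_length,
                 within_block_r = within_block_r, risk_loci = risk_loci,
                 baseline_prevalence = baseline_prevalence,
                 n_chromosomes = n_chromosomes,
                 marker_spacing_bp = marker_spacing_bp, seed = seed),
            class = "cohort_spec")
}

# marker map implied by a cohort_spec: markers split evenly over
# chromosomes, equally spaced
.spec_map <- function(spec, maf) {
  m <- spec$n_markers
  chr <- rep(seq_len(spec$n_chromosomes), length.out = m)
  chr <- sort(chr)
  pos <- as.integer(unlist(lapply(split(seq_len(m), chr), function(i)
    seq_along(i) * spec$marker_spacing_bp), use.names = FALSE))
  data.frame(chr = chr, snp = sprintf("snp%05d", seq_len(m)), cm = 0,
             pos = pos, a1 = "A", a2 = "B", maf = maf,
             stringsAsFactors = FALSE)
}

# one haplotype (0/1 vector of allele-1 indicators) under the
# first-order copying model; u is shared latent uniform machinery
.sim_haplotypes <- function(n_hap, freqs, block, r) {
  m <- length(freqs)
  U <- matrix(runif(n_hap * m), n_hap, m)
  if (r > 0 && m > 1) {
    for (j in 2:m) {
      same_block <- ((j - 1) %/% block) == ((j - 2) %/% block)
      if (same_block) {
        copy <- runif(n_hap) < r
        U[copy, j] <- U[copy, j - 1]
      }
    }
  }
  (U < rep(freqs, each = n_hap)) * 1L
}

# penetrance of a genotype row under the multiplicative risk model
.penetrance <- function(G, spec) {
  p <- rep(spec$baseline_prevalence, nrow(G))
  rl <- spec$risk_loci
  if (!is.null(rl)) {
    for (k in seq_len(nrow(rl))) {
      g <- G[, rl$marker[k]]
      x <- switch(rl$model[k],
                  additive = g,
                  dominant = as.integer(g >= 1),
                  recessive = as.integer(g == 2))
      p <- p * rl$rr[k]^x
    }
  }
  pmin(p, 1)
}

#' Simulate a pedigreed case/control cohort
#'
#' Founder genotypes are drawn at Hardy-Weinberg equilibrium from
#' block-correlated haplotypes; each child inherits one haplotype segment
#' per parent by fair Mendelian transmission (the transmitted parental
#' haplotype is chosen once per LD block, preserving within-block LD in
#' offspring while keeping transmission fair marker by marker). Affection
#' status is sampled from the multiplicative-risk penetrance model;
#' families are ascertained on having at least one affected child,
#' mirroring recruitment through an index patient, and singletons are
#' sampled conditional on their case/control label.
#'
#' @param spec a [cohort_spec()]
#' @return a [pedigree_cohort()]; the true per-marker allele-1
#'   frequencies are attached as attribute `"true_maf"`
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed)
  maf <- runif(spec$n_markers, spec$maf_range[1], spec$maf_range[2])
  map <- .spec_map(spec, maf)
  m <- spec$n_markers
  blk <- spec$ld_block_length
  n_blocks <- ceiling(m / blk)
  block_of <- ((seq_len(m) - 1) %/% blk) + 1

  ped_rows <- list(); geno_rows <- list()
  fam_counter <- 0L
  kids <- spec$children_per_family

  # simulate a batch of B families vectorized over families; children
  # inherit one parental haplotype per LD block (fair transmission,
  # within-block LD preserved)
  sim_family_batch <- function(B) {
    H <- .sim_haplotypes(4 * B, maf, blk, spec$within_block_r)
    i1 <- seq(1, 4 * B, 4)
    gF <- H[i1, , drop = FALSE] + H[i1 + 1, , drop = FALSE]
    gM <- H[i1 + 2, , drop = FALSE] + H[i1 + 3, , drop = FALSE]
    kid_list <- vector("list", kids)
    for (k in seq_len(kids)) {
      Pf <- matrix(runif(B * n_blocks) < 0.5, B, n_blocks)[, block_of, drop = FALSE]
      Pm <- matrix(runif(B * n_blocks) < 0.5, B, n_blocks)[, block_of, drop = FALSE]
      hf <- ifelse(Pf, H[i1, , drop = FALSE], H[i1 + 1, , drop = FALSE])
      hm <- ifelse(Pm, H[i1 + 2, , drop = FALSE], H[i1 + 3, , drop = FALSE])
      kid_list[[k]] <- hf + hm
    }
    aff_F <- 1L + (runif(B) < .penetrance(gF, spec))
    aff_M <- 1L + (runif(B) < .penetrance(gM, spec))
    aff_K <- vapply(kid_list, function(Gk)
      1L + (runif(B) < .penetrance(Gk, spec)), integer(B))
    if (B == 1) aff_K <- matrix(aff_K, 1, kids)
    list(gF = gF, gM = gM, kids = kid_list, aff_F = aff_F, aff_M = aff_M,
         aff_K = aff_K)
  }

  if (spec$n_families > 0) {
    need <- spec$n_families
    rounds <- 0L
    while (need > 0 && rounds < 200L) {
      rounds <- rounds + 1L
      B <- max(32L, 2L * need)
      bt <- sim_family_batch(B)
      ok <- which(rowSums(bt$aff_K == 2L) > 0)
      # after many rounds accept any family so the count is always met
      if (rounds >= 100L) ok <- seq_len(B)
      take <- head(ok, need)
      for (b in take) {
        fam_counter <- fam_counter + 1L
        fid <- sprintf("F%04d", fam_counter)
        iid <- c(paste0(fid, "_dad"), paste0(fid, "_mom"),
                 sprintf("%s_kid%d", fid, seq_len(kids)))
        ped_rows[[length(ped_rows) + 1]] <- data.frame(
          fid = fid, iid = iid,
          pid = c("0", "0", rep(iid[1], kids)),
          mid = c("0", "0", rep(iid[2], kids)),
          sex = c(1L, 2L, 1L + (runif(kids) < 0.5)),
          aff = c(bt$aff_F[b], bt$aff_M[b], bt$aff_K[b, ]),
          stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1]] <-
          rbind(bt$gF[b, ], bt$gM[b, ],
                do.call(rbind, lapply(bt$kids, function(Gk) Gk[b, ])))
      }
      need <- spec$n_families - fam_counter
    }
  }

  sample_singletons <- function(n, want_aff) {
    if (n == 0) return(NULL)
    out <- matrix(0L, n, m); got <- 0L
    while (got < n) {
      batch <- max(64L, 2L * (n - got))
      H <- .sim_haplotypes(2 * batch, maf, blk, spec$within_block_r)
      G <- H[seq_len(batch) * 2 - 1, , drop = FALSE] +
           H[seq_len(batch) * 2, , drop = FALSE]
      is_case <- runif(batch) < .penetrance(G, spec)
      keep <- which(is_case == want_aff)
      take <- head(keep, n - got)
      if (length(take)) {
        out[got + seq_along(take), ] <- G[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    out
  }
  for (grp in list(list(n = spec$n_unrelated_cases, aff = 2L, tag = "case"),
                   list(n = spec$n_unrelated_controls, aff = 1L, tag = "ctrl"))) {
    if (grp$n == 0) next
    G <- sample_singletons(grp$n, grp$aff == 2L)
    iid <- sprintf("U%s%04d", grp$tag, seq_len(grp$n))
    ped_rows[[length(ped_rows) + 1]] <- data.frame(
      fid = iid, iid = iid, pid = "0", mid = "0",
      sex = 1L + (runif(grp$n) < 0.5), aff = grp$aff,
      stringsAsFactors = FALSE)
    geno_rows[[length(geno_rows) + 1]] <- G
  }

  ped <- do.call(rbind, ped_rows)
  geno <- do.call(rbind, geno_rows)
  rownames(ped) <- NULL
  co <- pedigree_cohort(ped, geno, map[, c("chr", "snp", "cm", "pos", "a1", "a2")])
  attr(co, "true_maf") <- maf
  co
}

#' Artifact injection settings for quality-control testing
#'
#' Describes deliberate data corruptions — missing calls, heterozygosity
#' distortions, Mendelian errors and admixed ancestry — to be planted in
#' a clean synthetic cohort so the QC filters can be tested against a
#' known truth. Every injected artifact is logged with sample IDs so
#' tests can assert exact recovery.
#'
#' @param missing_rates named numeric vector (names = sample IDs) of
#'   per-sample missing-call rates in [0, 1]
#' @param het_outlier_fraction fraction of samples to turn into
#'   heterozygosity outliers, in [0, 1]
#' @param het_outlier_shift in (-1, 1): positive flips that share of
#'   homozygous calls to heterozygous (inflation), negative flips that
#'   share of heterozygous calls to homozygous (deflation)
#' @param mendel_errors named integer vector (names = child sample IDs)
#'   of Mendelian-error counts to inject into each child
#' @param admixed_fraction fraction of samples to make admixed, in [0, 1]
#' @param admixture_weight in [0, 1]: flagged samples are regenotyped
#'   from frequencies `(1-w) f + w u` with `u` a second population's
#'   frequencies drawn once per marker
#' @param seed integer seed
#' @return an object of class `artifact_spec`
#' @export
artifact_spec <- function(missing_rates = NULL, het_outlier_fraction = 0,
                          het_outlier_shift = 0.3, mendel_errors = NULL,
                          admixed_fraction = 0, admixture_weight = 0.5,
                          seed = 1) {
  if (!is.null(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates > 1)))
    stop("invalid artifact_spec field 'missing_rates': rates must be in [0, 1]")
  for (f in c("het_outlier_fraction", "admixed_fraction", "admixture_weight")) {
    v <- get(f)
    if (v < 0 || v > 1)
      stop("invalid artifact_spec field '", f, "': must be in [0, 1]")
  }
  if (abs(het_outlier_shift) >= 1)
    stop("invalid artifact_spec field 'het_outlier_shift': must be in (-1, 1)")
  if (!is.null(mendel_errors) && any(mendel_errors < 0))
    stop("invalid artifact_spec field 'mendel_errors': counts must be >= 0")
  structure(list(missing_rates = missing_rates,
                 het_outlier_fraction = het_outlier_fraction,
                 het_outlier_shift = het_outlier_shift,
                 mendel_errors = mendel_errors,
                 admixed_fraction = admixed_fraction,
                 admixture_weight = admixture_weight, seed = seed),
            class = "artifact_spec")
}

#' Inject QC artifacts into a cohort
#'
#' Applies the corruptions described by an [artifact_spec()] and returns
#' the corrupted cohort together with a log of exactly what was changed.
#' The input object is not modified. Order of application: admixture
#' resampling, heterozygosity distortion, Mendelian errors, then missing
#' calls (so a missing call can mask an injected Mendel error, which the
#' log records verbatim).
#'
#' @param cohort a [pedigree_cohort()]
#' @param spec an [artifact_spec()]
#' @return list with elements `cohort` (corrupted copy) and `log` (list
#'   with `missing` data.frame (iid, marker), `het_outliers` character,
#'   `mendel` data.frame (iid, marker), `admixed` character)
#' @export
inject_qc_artifacts <- function(cohort, spec) {
  if (!inherits(spec, "artifact_spec")) stop("spec must be an artifact_spec")
  if (n_samples(cohort) == 0) stop("cohort is empty")
  set.seed(spec$seed)
  G <- cohort$geno
  m <- ncol(G)
  log <- list(missing = data.frame(iid = character(), marker = character()),
              het_outliers = character(),
              mendel = data.frame(iid = character(), marker = character()),
              admixed = character())

  n_adm <- round(spec$admixed_fraction * nrow(G))
  if (n_adm > 0) {
    adm <- sample(rownames(G), n_adm)
    f <- colMeans(G, na.rm = TRUE) / 2
    u <- runif(m)
    f2 <- (1 - spec$admixture_weight) * f + spec$admixture_weight * u
    for (s in adm) G[s, ] <- rbinom(m, 2, f2)
    log$admixed <- sort(adm)
  }

  n_het <- round(spec$het_outlier_fraction * nrow(G))
  if (n_het > 0) {
    pool <- setdiff(rownames(G), log$admixed)
    if (n_het > length(pool)) stop("requested more het outliers than available samples")
    hs <- sample(pool, n_het)
    for (s in hs) {
      g <- G[s, ]
      if (spec$het_outlier_shift > 0) {
        idx <- which(!is.na(g) & g != 1)
        flip <- idx[runif(length(idx)) < spec$het_outlier_shift]
        g[flip] <- 1L
      } else {
        idx <- which(!is.na(g) & g == 1)
        flip <- idx[runif(length(idx)) < -spec$het_outlier_shift]
        g[flip] <- ifelse(runif(length(flip)) < 0.5, 0L, 2L)
      }
      G[s, ] <- g
    }
    log$het_outliers <- sort(hs)
  }

  if (!is.null(spec$mendel_errors) && length(spec$mendel_errors)) {
    ids <- names(spec$mendel_errors)
    bad <- setdiff(ids, cohort$ped$iid)
    if (length(bad)) stop("mendel_errors names unknown: ", paste(bad, collapse = ", "))
    rows <- list()
    for (s in ids) {
      k <- spec$mendel_errors[[s]]
      if (k == 0) next
      i <- match(s, cohort$ped$iid)
      pid <- cohort$ped$pid[i]; mid <- cohort$ped$mid[i]
      if (pid == "0" && mid == "0")
        stop("sample ", s, " has no genotyped parents; cannot inject Mendel errors")
      gF <- if (pid != "0") G[pid, ] else rep(NA_integer_, m)
      gM <- if (mid != "0") G[mid, ] else rep(NA_integer_, m)
      # for each marker the set of Mendel-consistent child dosages
      inconsistent_choice <- function(j) {
        tf <- .transmissible(gF[j]); tm <- .transmissible(gM[j])
        ok <- unique(outer(tf, tm, "+"))
        bad <- setdiff(0:2, ok)
        if (length(bad)) bad[sample.int(length(bad), 1)] else NA_integer_
      }
      cand <- sample(seq_len(m))
      placed <- 0L
      for (j in cand) {
        if (placed >= k) break
        v <- inconsistent_choice(j)
        if (!is.na(v)) {
          G[s, j] <- v
          rows[[length(rows) + 1]] <- data.frame(
            iid = s, marker = cohort$map$snp[j], stringsAsFactors = FALSE)
          placed <- placed + 1L
        }
      }
      if (placed < k)
        warning("only ", placed, " of ", k,
                " Mendel errors injectable for sample ", s)
    }
    if (length(rows)) log$mendel <- do.call(rbind, rows)
  }

  if (!is.null(spec$missing_rates) && length(spec$missing_rates)) {
    ids <- names(spec$missing_rates)
    bad <- setdiff(ids, cohort$ped$iid)
    if (length(bad)) stop("missing_rates names unknown: ", paste(bad, collapse = ", "))
    rows <- list()
    for (s in ids) {
      r <- spec$missing_rates[[s]]
      k <- round(r * m)
      if (k == 0) next
      j <- sample(seq_len(m), k)
      G[s, j] <- NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        iid = s, marker = cohort$map$snp[j], stringsAsFactors = FALSE)
    }
    if (length(rows)) log$missing <- do.call(rbind, rows)
  }

  out <- cohort
  out$geno <- G
  list(cohort = out, log = log)
}

# alleles a parent with dosage g can transmit (dosage-of-allele-1 units);
# an ungenotyped/missing parent can transmit either allele
.transmissible <- function(g) {
  if (is.na(g)) c(0L, 1L)
  else if (g == 0) 0L
  else if (g == 2) 1L
  else c(0L, 1L)
}

#' eQTL catalogue simulation settings
#'
#' Describes a synthetic catalogue of SNP-to-gene regulatory
#' associations: per gene a set of marker SNPs with a signed effect size
#' for a stated effect allele, a p-value, tissue label(s), and (for the
#' blood-style dialect) an FDR column.
#'
#' @param n_genes number of genes
#' @param snps_per_gene integer, or length-2 range from which each gene's
#'   SNP count is drawn uniformly
#' @param effect_size_sd scale of the Gaussian signed effects (beta)
#' @param significant_fraction fraction of records whose p is drawn from
#'   Uniform(0, 0.05); the rest are Uniform(0, 1]
#' @param dialect `"muther"` (LCL + skin rows per SNP-gene pair, no FDR)
#'   or `"blood"` (single tissue with an FDR column)
#' @param seed integer seed
#' @return an object of class `eqtl_catalogue_spec`
#' @export
eqtl_catalogue_spec <- function(n_genes = 100, snps_per_gene = c(10, 30),
                                effect_size_sd = 0.2,
                                significant_fraction = 0.5,
                                dialect = c("blood", "muther"), seed = 1) {
  dialect <- match.arg(dialect)
  if (n_genes < 0) stop("invalid eqtl_catalogue_spec field 'n_genes': must be >= 0")
  if (any(snps_per_gene < 1)) stop("invalid eqtl_catalogue_spec field 'snps_per_gene': must be >= 1")
  if (effect_size_sd <= 0) stop("invalid eqtl_catalogue_spec field 'effect_size_sd': must be > 0")
  if (significant_fraction < 0 || significant_fraction > 1)
    stop("invalid eqtl_catalogue_spec field 'significant_fraction': must be in [0, 1]")
  structure(list(n_genes = n_genes, snps_per_gene = snps_per_gene,
                 effect_size_sd = effect_size_sd,
                 significant_fraction = significant_fraction,
                 dialect = dialect, seed = seed),
            class = "eqtl_catalogue_spec")
}

#' Simulate an eQTL catalogue over a cohort's markers
#'
#' Draws, per gene, a set of SNPs from the cohort map with signed
#' Gaussian effects for a randomly chosen effect allele. Under the null
#' the effect direction is independent of case/control allele
#' frequencies. A planted directed association can be requested: for the
#' genes named in `planted`, each record's effect allele is set to the
#' allele that is more frequent in cases and its beta is forced to the
#' requested sign, so the gene's SNPs concentrate in one directed bin.
#'
#' @param spec an [eqtl_catalogue_spec()]
#' @param cohort a [pedigree_cohort()] supplying markers (and, for
#'   planted genes, case/control frequencies)
#' @param planted optional named character vector: names are gene names
#'   (must be among the generated genes, i.e. `gene0001` ...), values
#'   `"up"` or `"down"` — the regulatory direction to plant for the
#'   case-enriched allele
#' @return data.frame of eQTL records with columns `snp`, `gene`,
#'   `effect_allele`, `beta`, `p`, `tissue`, and `fdr` (blood dialect);
#'   planted record positions are attached as attribute `"planted_log"`
#' @export
simulate_eqtl_catalogue <- function(spec, cohort, planted = NULL) {
  if (!inherits(spec, "eqtl_catalogue_spec"))
    stop("spec must be an eqtl_catalogue_spec")
  set.seed(spec$seed)
  if (spec$n_genes == 0)
    return(data.frame(snp = character(), gene = character(),
                      effect_allele = character(), beta = numeric(),
                      p = numeric(), tissue = character(),
                      stringsAsFactors = FALSE))
  map <- cohort$map
  nm <- nrow(map)
  rng <- if (length(spec$snps_per_gene) == 1)
    rep(spec$snps_per_gene, 2) else spec$snps_per_gene
  if (rng[2] > nm)
    stop("snps_per_gene exceeds the number of available markers (", nm, ")")
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  if (!is.null(planted)) {
    bad <- setdiff(names(planted), genes)
    if (length(bad)) stop("planted gene(s) not in catalogue: ",
                          paste(bad, collapse = ", "))
    if (!all(planted %in% c("up", "down")))
      stop("planted directions must be 'up' or 'down'")
    freqs <- snp_freq_table(cohort)
  }
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    k <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    j <- sample(nm, k)
    pick_a1 <- runif(k) < 0.5
    allele <- ifelse(pick_a1, map$a1[j], map$a2[j])
    beta <- rnorm(k, 0, spec$effect_size_sd)
    if (!is.null(planted) && g %in% names(planted)) {
      dirn <- planted[[g]]
      case_up <- freqs$freq_a1_cases[j] > freqs$freq_a1_controls[j]
      allele <- ifelse(case_up, map$a1[j], map$a2[j])
      beta <- abs(beta) * if (dirn == "up") 1 else -1
    }
    sig <- runif(k) < spec$significant_fraction
    p <- ifelse(sig, runif(k, 0, 0.05), runif(k))
    p <- pmax(p, .Machine$double.xmin)  # p in (0, 1]
    if (spec$dialect == "blood") {
      rows[[gi]] <- data.frame(snp = map$snp[j], gene = g,
                               effect_allele = allele, beta = beta, p = p,
                               tissue = "blood",
                               fdr = ifelse(sig, runif(k, 0, 0.4), runif(k)),
                               stringsAsFactors = FALSE)
    } else {
      # two tissue rows per SNP-gene pair; the more significant tissue
      # carries the generated record, the other an attenuated one
      p2 <- pmin(1, p * (1 + runif(k, 0.5, 10)))
      beta2 <- beta * runif(k, 0.3, 1)
      first_lcl <- runif(k) < 0.5
      rows[[gi]] <- data.frame(
        snp = rep(map$snp[j], 2), gene = g,
        effect_allele = rep(allele, 2),
        beta = c(ifelse(first_lcl, beta, beta2),
                 ifelse(first_lcl, beta2, beta)),
        p = c(ifelse(first_lcl, p, p2), ifelse(first_lcl, p2, p)),
        tissue = rep(c("LCL", "skin"), each = k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(planted))
    attr(out, "planted_log") <- out[out$gene %in% names(planted) &
                                      out$tissue != "skin", c("snp", "gene")]
  out
}

#' Expression-matrix simulation settings
#'
#' @param n_case_samples,n_control_samples group sizes
#' @param n_probes number of probes
#' @param de_probes data.frame with columns `probe` (1-based probe index)
#'   and `log2fc` (shift added to case samples), or NULL for a null matrix
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0)
#' @param genes character vector of gene names probes are mapped onto
#'   (round-robin); defaults to one gene per probe
#' @param baseline_mean mean log2 intensity
#' @param seed integer seed
#' @return an object of class `expression_spec`
#' @export
expression_spec <- function(n_case_samples = 20, n_control_samples = 17,
                            n_probes = 1000, de_probes = NULL,
                            noise_sd = 0.3, genes = NULL,
                            baseline_mean = 8, seed = 1) {
  if (noise_sd <= 0) stop("invalid expression_spec field 'noise_sd': must be > 0")
  if (n_probes < 1) stop("invalid expression_spec field 'n_probes': must be >= 1")
  if (!is.null(de_probes)) {
    if (!all(c("probe", "log2fc") %in% names(de_probes)))
      stop("invalid expression_spec field 'de_probes': needs probe, log2fc")
    if (any(de_probes$probe < 1 | de_probes$probe > n_probes))
      stop("invalid expression_spec field 'de_probes': probe index out of range")
  }
  structure(list(n_case_samples = n_case_samples,
                 n_control_samples = n_control_samples,
                 n_probes = n_probes, de_probes = de_probes,
                 noise_sd = noise_sd, genes = genes,
                 baseline_mean = baseline_mean, seed = seed),
            class = "expression_spec")
}

#' Simulate a probe-level expression matrix
#'
#' Gaussian log2-scale intensities with per-probe baselines; probes
#' listed in `de_probes` are shifted by their log2 fold change in the
#' case samples only.
#'
#' @param spec an [expression_spec()]
#' @return list with `expr` (matrix probes x samples), `groups` (named
#'   character vector, "case"/"control" per sample), `probe_map`
#'   (data.frame probe, gene)
#' @export
simulate_expression_matrix <- function(spec) {
  if (!inherits(spec, "expression_spec")) stop("spec must be an expression_spec")
  set.seed(spec$seed)
  np <- spec$n_probes
  ns <- spec$n_case_samples + spec$n_control_samples
  base <- rnorm(np, spec$baseline_mean, 1)
  expr <- matrix(rnorm(np * ns, 0, spec$noise_sd), np, ns) + base
  samples <- c(sprintf("case%02d", seq_len(spec$n_case_samples)),
               sprintf("ctrl%02d", seq_len(spec$n_control_samples)))
  groups <- setNames(rep(c("case", "control"),
                         c(spec$n_case_samples, spec$n_control_samples)),
                     samples)
  if (!is.null(spec$de_probes) && nrow(spec$de_probes))
    expr[spec$de_probes$probe, seq_len(spec$n_case_samples)] <-
      expr[spec$de_probes$probe, seq_len(spec$n_case_samples), drop = FALSE] +
      spec$de_probes$log2fc
  probes <- sprintf("probe%05d", seq_len(np))
  dimnames(expr) <- list(probes, samples)
  genes <- if (is.null(spec$genes)) sprintf("gene%04d", seq_len(np)) else spec$genes
  probe_map <- data.frame(probe = probes,
                          gene = rep(genes, length.out = np),
                          stringsAsFactors = FALSE)
  list(expr = expr, groups = groups, probe_map = probe_map)
}

#' Simulate gene annotations on a cohort's genome
#'
#' Places genes of the given length uniformly over the chromosomes
#' spanned by the cohort map (BED-style 0-based half-open coordinates).
#'
#' @param cohort a [pedigree_cohort()]
#' @param n_genes number of genes
#' @param gene_length_bp gene length in base pairs
#' @param seed integer seed
#' @return data.frame with columns `chr`, `start`, `end`, `gene`
#'   (0-based half-open)
#' @export
simulate_genes <- function(cohort, n_genes = 200, gene_length_bp = 2000,
                           seed = 1) {
  set.seed(seed)
  map <- cohort$map
  chr_len <- tapply(map$pos, map$chr, max) + gene_length_bp
  chrs <- as.integer(names(chr_len))
  chr <- sample(chrs, n_genes, replace = TRUE, prob = as.numeric(chr_len))
  start <- floor(runif(n_genes) * (chr_len[as.character(chr)] - gene_length_bp))
  out <- data.frame(chr = chr, start = as.integer(start),
                    end = as.integer(start + gene_length_bp),
                    gene = sprintf("gene%04d", seq_len(n_genes)),
                    stringsAsFactors = FALSE)
  out[order(out$chr, out$start), , drop = FALSE]
}

#' Simulate gene-set collections
#'
#' @param genes character vector of gene names to draw from
#' @param n_sets number of gene sets
#' @param set_size integer, or length-2 range of set sizes
#' @param source label recorded for the collection ("GO", "KEGG", ...)
#' @param seed integer seed
#' @return data.frame with columns `set`, `source`, `gene` (long format)
#' @export
simulate_gene_sets <- function(genes, n_sets = 20, set_size = c(5, 20),
                               source = "GO", seed = 1) {
  set.seed(seed)
  rng <- if (length(set_size) == 1) rep(set_size, 2) else set_size
  rows <- lapply(seq_len(n_sets), function(i) {
    k <- min(length(genes),
             if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1))
    data.frame(set = sprintf("%s_set%03d", source, i), source = source,
               gene = sample(genes, k), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate an unrelated case/control cohort with planted frequency shifts
#'
#' Builds a cohort of unrelated cases and controls in which selected
#' markers have their allele-1 frequency raised by `shift` in cases
#' (controls keep the base frequency). This is the construction used to
#' test the directed eQTL enrichment: the frequency difference is planted
#' directly rather than through a penetrance model, so its size is exact
#' by design.
#'
#' @param n_cases,n_controls group sizes
#' @param n_markers marker count
#' @param maf base allele-1 frequency for all markers
#' @param shifted_markers integer indices of markers shifted in cases
#' @param shift added to the case-group allele-1 frequency
#' @param seed integer seed
#' @return a [pedigree_cohort()] of singletons
#' @export
simulate_freq_shift_cohort <- function(n_cases = 400, n_controls = 400,
                                       n_markers = 500, maf = 0.3,
                                       shifted_markers = integer(),
                                       shift = 0.1, seed = 1) {
  set.seed(seed)
  f_case <- rep(maf, n_markers)
  f_case[shifted_markers] <- pmin(0.99, maf + shift)
  Gc <- sapply(f_case, function(f) rbinom(n_cases, 2, f))
  Gu <- sapply(rep(maf, n_markers), function(f) rbinom(n_controls, 2, f))
  G <- rbind(Gc, Gu)
  iid <- c(sprintf("case%04d", seq_len(n_cases)),
           sprintf("ctrl%04d", seq_len(n_controls)))
  ped <- data.frame(fid = iid, iid = iid, pid = "0", mid = "0",
                    sex = 1L, aff = rep(c(2L, 1L), c(n_cases, n_controls)),
                    stringsAsFactors = FALSE)
  map <- data.frame(chr = 1L, snp = sprintf("snp%05d", seq_len(n_markers)),
                    cm = 0, pos = seq_len(n_markers) * 5000L,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  pedigree_cohort(ped, G, map)
}
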