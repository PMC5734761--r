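test_that("multi-tissue filter keeps the more significant tissue then applies thresholds", {
  rec <- data.frame(
    snp = c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4"),
    gene = "g1",
    effect_allele = "A",
    beta = c(0.5, 0.4, 0.02, 0.3, 0.005, 0.004, 0.2, 0.1),
    p = c(0.01, 0.001, 0.04, 0.2, 0.01, 0.2, 0.05, 0.2),
    tissue = rep(c("LCL", "skin"), 4),
    stringsAsFactors = FALSE)
  out <- filter_muther(rec)
  # s1: skin has the smaller p -> LCL discarded
  expect_identical(out$tissue[out$snp == "s1"], "skin")
  # s3: survives tissue choice but |beta| < 0.01 -> dropped
  expect_false("s3" %in% out$snp)
  # s4: p = 0.05 exactly is kept (strict "> 0.05" exclusion)
  expect_true("s4" %in% out$snp)
  expect_identical(out$tissue[out$snp == "s4"], "LCL")
  # duplicates error
  expect_error(filter_muther(rec[c(1, 1, 2), ]), "duplicate")
  expect_error(filter_muther(transform(rec, tissue = "adipose")), "LCL or skin")
})

test_that("blood filter is FDR-only", {
  rec <- data.frame(snp = c("s1", "s2", "s3"), gene = "g",
                    effect_allele = "A", beta = c(0.001, 1, 0.5),
                    p = c(0.9, 0.2, 0.01), tissue = "blood",
                    fdr = c(0.1, 0.49, 0.51), stringsAsFactors = FALSE)
  out <- filter_blood(rec)
  expect_setequal(out$snp, c("s1", "s2"))  # tiny beta kept; fdr 0.51 dropped
  expect_identical(nrow(filter_blood(rec[0, ])), 0L)
  expect_error(filter_blood(rec[, -7]), "fdr")
})

test_that("case/control allele frequency is plain counting over all individuals", {
  ped <- data.frame(fid = c("a", "b", "c", "d"), iid = c("a", "b", "c", "d"),
                    pid = "0", mid = "0", sex = 1L,
                    aff = c(2L, 2L, 1L, 1L))
  G <- matrix(c(2L, 1L,   # cases: AA, AB -> freq(A) = 3/4
                0L, NA), 4, 1)
  map <- data.frame(chr = 1L, snp = "rs1", cm = 0, pos = 100L,
                    a1 = "A", a2 = "B")
  co <- pedigree_cohort(ped, G, map)
  fr <- case_control_allele_freq(co, "rs1", "A")
  expect_equal(unname(fr["cases"]), 3 / 4)
  expect_equal(unname(fr["controls"]), 0)
  fr2 <- case_control_allele_freq(co, "rs1", "B")
  expect_equal(unname(fr2["cases"]), 1 / 4)
  expect_error(case_control_allele_freq(co, "rs9", "A"), "rs9")
  expect_error(case_control_allele_freq(co, "rs1", "C"), "not one of")
  co$geno[3:4, 1] <- NA
  expect_warning(fr3 <- case_control_allele_freq(co, "rs1", "A"),
                 "controls")
  expect_true(is.nan(fr3[["controls"]]))
})

test_that("directed contingency binning follows the sign and tie rules", {
  co <- simulate_freq_shift_cohort(n_cases = 200, n_controls = 200,
                                   n_markers = 10, maf = 0.3,
                                   shifted_markers = 1:3, shift = 0.2,
                                   seed = 191)
  fr <- snp_freq_table(co)
  up_snps <- fr$snp[1:3]       # planted higher allele-1 freq in cases
  rec <- data.frame(snp = up_snps, gene = "g1", effect_allele = "A",
                    beta = 1, p = 0.01, tissue = "blood",
                    stringsAsFactors = FALSE)
  tab <- build_contingency("g1", rec, co)
  expect_identical(tab[["up_plus"]], 3L)
  expect_identical(sum(tab), 3L)
  # beta = 0 excluded with a warning; empty gene gives the zero table
  rec0 <- transform(rec, beta = 0)
  expect_warning(tab0 <- build_contingency("g1", rec0, co), "beta = 0")
  expect_identical(sum(tab0), 0L)
  expect_identical(sum(build_contingency("absent", rec, co)), 0L)
  expect_equal(fisher_exact_two_sided(build_contingency("absent", rec, co)), 1)

  # exactly equal frequencies fall in the "-" bin
  ped <- data.frame(fid = c("a", "b"), iid = c("a", "b"), pid = "0",
                    mid = "0", sex = 1L, aff = c(2L, 1L))
  G <- matrix(c(1L, 1L), 2, 1)
  map <- data.frame(chr = 1L, snp = "rs1", cm = 0, pos = 1L,
                    a1 = "A", a2 = "B")
  co2 <- pedigree_cohort(ped, G, map)
  rec2 <- data.frame(snp = "rs1", gene = "g", effect_allele = "A",
                     beta = 1, p = 0.01, tissue = "blood",
                     stringsAsFactors = FALSE)
  tab2 <- build_contingency("g", rec2, co2)
  expect_identical(tab2[["up_minus"]], 1L)
})

test_that("two-sided Fisher p matches exhaustive enumeration for all tables up to n = 16", {
  for (n in 0:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_exact_two_sided(c(a, b, c, d)),
                   oracle_fisher_two_sided(a, b, c, d),
                   tolerance = 1e-12,
                   info = paste(a, b, c, d))
    }
  }
})

test_that("two-sided Fisher p matches stats::fisher.test on random tables", {
  set.seed(201)
  for (i in 1:200) {
    x <- as.integer(rmultinom(1, sample(5:80, 1), runif(4, 0.05, 1)))
    expect_equal(fisher_exact_two_sided(x),
                 fisher.test(matrix(x, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9, info = paste(x, collapse = ","))
  }
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact_two_sided(c(0, 0, 3, 4)), 1)  # zero row
  expect_error(fisher_exact_two_sided(c(-1, 1, 1, 1)), "negative")
})

test_that("empirical p follows the (r+1)/(N+1) rule and its escalation pool", {
  co <- simulate_freq_shift_cohort(n_cases = 150, n_controls = 150,
                                   n_markers = 400, seed = 211)
  cata <- simulate_eqtl_catalogue(
    eqtl_catalogue_spec(n_genes = 120, snps_per_gene = c(5, 12),
                        dialect = "blood", significant_fraction = 0.3,
                        seed = 213), co)
  rec <- filter_blood(cata)
  counts <- table(rec$gene)
  g <- names(counts)[which(counts == stats::median(counts))[1]]
  res <- empirical_enrichment_p(g, rec, co, N = 50, seed = 215)
  expect_equal(res$empirical_p, (1 + res$n_leq) / (res$n_null + 1))
  expect_gte(res$empirical_p, 1 / (res$n_null + 1))
  expect_lte(res$empirical_p, 1)
  # reproducible bit-for-bit given (seed, N)
  res2 <- empirical_enrichment_p(g, rec, co, N = 50, seed = 215)
  expect_identical(res, res2)
  # escalation: the pool grows through n+1, n+2, ... SNP genes but can
  # never include genes with fewer SNPs than the target
  achievable <- sum(counts[names(counts) != g] >= res$n_snps)
  res3 <- suppressWarnings(
    empirical_enrichment_p(g, rec, co, N = 100, seed = 217))
  expect_identical(res3$n_null, min(100L, achievable))
  expect_gte(res3$n_null, res$n_null)
  # asking for more nulls than the catalogue holds warns and uses all
  expect_warning(res4 <- empirical_enrichment_p(g, rec, co, N = 5000,
                                                seed = 219),
                 "null genes available")
  expect_lt(res4$n_null, 5000L)
  expect_error(empirical_enrichment_p("nonexistent", rec, co), "no filtered")
})

test_that("empirical eQTL p is valid and rank-calibrated under an exchangeable catalogue", {
  # Fisher's p on a small 2x2 is discrete with a large atom at 1, so the
  # tie-inclusive empirical p is deliberately conservative (sub-uniform)
  # rather than exactly uniform. Calibration is checked two ways.
  # (1) validity of the reported p on one realistic shared catalogue
  co <- simulate_freq_shift_cohort(n_cases = 200, n_controls = 200,
                                   n_markers = 600, seed = 221)
  cata <- simulate_eqtl_catalogue(
    eqtl_catalogue_spec(n_genes = 300, snps_per_gene = c(8, 12),
                        dialect = "blood", significant_fraction = 0.3,
                        seed = 223), co)
  rec <- filter_blood(cata)
  freqs <- snp_freq_table(co)
  set.seed(229)
  genes <- sample(unique(rec$gene), 100)
  pvals <- vapply(seq_along(genes), function(i)
    suppressWarnings(
      empirical_enrichment_p(genes[i], rec, co, N = 200, seed = 7000 + i,
                             freqs = freqs))$empirical_p, numeric(1))
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    slack <- 2.6 * sqrt(t * (1 - t) / 100)
    expect_lte(mean(pvals <= t), t + slack)
  }
  expect_true(all(pvals > 0 & pvals <= 1))

  # (2) exact uniformity of the tie-randomized rank over independent
  # replicates (independent cohort + catalogue per target, so the KS
  # test's i.i.d. assumption holds)
  reps <- 150
  set.seed(233)
  U <- runif(reps)
  prand <- numeric(reps)
  for (r in seq_len(reps)) {
    co_r <- simulate_freq_shift_cohort(n_cases = 150, n_controls = 150,
                                       n_markers = 400, seed = 30000 + r)
    cat_r <- simulate_eqtl_catalogue(
      eqtl_catalogue_spec(n_genes = 120, snps_per_gene = c(5, 15),
                          dialect = "blood", significant_fraction = 0,
                          seed = 31000 + r), co_r)
    counts <- table(cat_r$gene)
    g <- names(sort(counts))[10]   # low count: pool always available
    res <- suppressWarnings(
      empirical_enrichment_p(g, cat_r, co_r, N = 100, seed = 32000 + r))
    prand[r] <- (res$n_less + U[r] * (res$n_leq - res$n_less + 1)) /
      (res$n_null + 1)
  }
  ks <- suppressWarnings(ks.test(prand, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted directed gene attains empirical significance", {
  n_seeds <- 50
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    co <- simulate_freq_shift_cohort(n_cases = 400, n_controls = 400,
                                     n_markers = 400, maf = 0.3,
                                     shifted_markers = 1:25, shift = 0.1,
                                     seed = 800 + s)
    # planted directed signal: down-regulating records carry the
    # case-enriched allele (Down+), up-regulating records carry the
    # allele depleted in cases (Up-); both margins stay populated so
    # the 2x2 dependence is testable
    planted <- data.frame(snp = co$map$snp[1:25], gene = "target",
                          effect_allele = c(rep("A", 13), rep("B", 12)),
                          beta = c(rep(-0.5, 13), rep(0.5, 12)),
                          p = 0.001, tissue = "blood", fdr = 0.01,
                          stringsAsFactors = FALSE)
    null_cat <- simulate_eqtl_catalogue(
      eqtl_catalogue_spec(n_genes = 120, snps_per_gene = 25,
                          dialect = "blood", significant_fraction = 1,
                          seed = 900 + s),
      subset_cohort(co, markers = co$map$snp[26:400]))
    rec <- filter_blood(rbind(planted, null_cat))
    res <- empirical_enrichment_p("target", rec, co, N = 100,
                                  seed = 1000 + s)
    if (res$empirical_p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the scan table carries contingency cells that sum to the SNP count", {
  co <- simulate_freq_shift_cohort(n_cases = 150, n_controls = 150,
                                   n_markers = 300, seed = 231)
  cata <- simulate_eqtl_catalogue(
    eqtl_catalogue_spec(n_genes = 60, snps_per_gene = c(5, 10),
                        dialect = "blood", seed = 233), co)
  rec <- filter_blood(cata)
  targets <- head(unique(rec$gene), 5)
  out <- suppressWarnings(
    eqtl_enrichment_scan(targets, rec, co, N = 30, seed = 235,
                         log2fc = setNames(rep(-0.5, 5), targets)))
  expect_identical(out$up_plus + out$up_minus + out$down_plus + out$down_minus,
                   out$n_snps)
  expect_true(all(out$fisher_p > 0 & out$fisher_p <= 1))
  expect_true(all(out$empirical_p > 0 & out$empirical_p <= 1))
  expect_true(!is.unsorted(out$empirical_p))
})
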