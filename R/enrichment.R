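#' Select the top-k markers by association p-value
#'
#' Ranked by ascending p; ties at the cutoff are broken by (chromosome,
#' position) order. With fewer than `k` results, all are returned with a
#' warning.
#'
#' @param results association results with columns `snp`, `chr`, `bp`, `p`
#' @param k number of markers to keep (default 1000)
#' @return character vector of marker IDs
#' @export
select_top_snps <- function(results, k = 1000) {
  if (nrow(results) < k) {
    warning("only ", nrow(results), " results available; taking all")
    k <- nrow(results)
  }
  ord <- order(results$p, results$chr, results$bp)
  results$snp[ord][seq_len(k)]
}

#' Build LD intervals from top markers
#'
#' A graph is formed over the selected markers with an edge wherever a
#' same-chromosome pair has dosage r-squared above `r2_min`; connected
#' components (chains of pairwise-high-LD markers) become intervals
#' spanning the members' minimum and maximum positions (1-based
#' inclusive). A singleton becomes a 1-bp interval.
#'
#' @param markers character vector of marker IDs (e.g. from
#'   [select_top_snps()])
#' @param cohort a [pedigree_cohort()] supplying genotypes for r-squared
#' @param r2_min LD threshold (default 0.25; strict `>`)
#' @return data.frame with one row per interval: `chr`, `start`, `end`,
#'   `n_snps`, `length`, `snp_density` (markers on the array within the
#'   interval, divided by length), `snps` (comma-joined member IDs);
#'   rows ordered by (chr, start)
#' @export
build_ld_intervals <- function(markers, cohort, r2_min = 0.25) {
  markers <- sort(unique(as.character(markers)))
  idx <- match(markers, cohort$map$snp)
  if (anyNA(idx)) stop("markers absent from cohort: ",
                       paste(head(markers[is.na(idx)]), collapse = ", "))
  chr <- cohort$map$chr[idx]; pos <- cohort$map$pos[idx]
  nm <- length(markers)
  # union-find over components
  parent <- seq_len(nm)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (c in unique(chr)) {
    on_c <- which(chr == c)
    if (length(on_c) < 2) next
    R2 <- suppressWarnings(cor(cohort$geno[, idx[on_c], drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    R2[is.na(R2)] <- 0
    for (a in seq_along(on_c))
      for (b in seq_len(a - 1))
        if (R2[a, b] > r2_min) union_(on_c[a], on_c[b])
  }
  comp <- vapply(seq_len(nm), find, integer(1))
  rows <- lapply(split(seq_len(nm), comp), function(mem) {
    st <- as.integer(min(pos[mem])); en <- as.integer(max(pos[mem]))
    in_iv <- cohort$map$chr == chr[mem[1]] &
      cohort$map$pos >= st & cohort$map$pos <= en
    len <- en - st + 1L
    data.frame(chr = chr[mem[1]], start = st, end = en,
               n_snps = length(mem), length = len,
               snp_density = sum(in_iv) / len,
               snps = paste(sort(markers[mem]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pinned coordinate convention: a 1-based inclusive interval [s, e] is
# compared as the half-open [s, e+1) directly against BED half-open
# gene coordinates (optionally padded)
.interval_gene_overlap <- function(iv_start, iv_end, g_start, g_end, pad = 0) {
  (g_start - pad) < (iv_end + 1) & (g_end + pad) > iv_start
}

#' Map LD intervals to overlapping genes
#'
#' @param intervals data.frame from [build_ld_intervals()]
#' @param genes gene coordinates (BED dialect, 0-based half-open) as from
#'   [read_gene_bed()]: columns `chr`, `start`, `end`, `gene`
#' @param pad_bp symmetric gene padding in base pairs (default 0)
#' @return data.frame with one row per (interval, gene) overlap:
#'   `interval` (row index into `intervals`), `chr`, `start`, `end`, `gene`
#' @export
map_intervals_to_genes <- function(intervals, genes, pad_bp = 0) {
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    on_c <- genes[genes$chr == intervals$chr[i], , drop = FALSE]
    hit <- .interval_gene_overlap(intervals$start[i], intervals$end[i],
                                  on_c$start, on_c$end, pad_bp)
    if (any(hit))
      rows[[length(rows) + 1]] <- data.frame(
        interval = i, chr = intervals$chr[i], start = intervals$start[i],
        end = intervals$end[i], gene = on_c$gene[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(interval = integer(), chr = integer(),
                      start = integer(), end = integer(),
                      gene = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome model for matched random-region placement
#'
#' @param cohort a [pedigree_cohort()]: chromosome lengths are taken as
#'   the maximum marker position per chromosome (plus one spacing unit)
#' @return list with `chr_len` (named lengths) and `positions` (list of
#'   sorted marker positions per chromosome)
#' @export
genome_model <- function(cohort) {
  map <- cohort$map
  pos <- split(map$pos, map$chr)
  pos <- lapply(pos, sort)
  gap <- stats::median(diff(pos[[1]]))
  if (!is.finite(gap) || gap <= 0) gap <- 1
  list(chr_len = vapply(pos, max, numeric(1)) + gap, positions = pos)
}

# batch-sample `n` random regions matched to (len, dens) within
# tolerance. Proposals alternate between a uniform start and a
# marker-anchored start (a random marker covered at a random offset), so
# short high-density templates — a 1-bp singleton interval has density 1
# — still have feasible proposals; acceptance enforces the density
# match. Returns a data.frame of `n` placements, or fewer if none are
# feasible within `max_chunks` proposal rounds.
.place_matched_batch <- function(gm, len, dens, tol, n, max_chunks = 60) {
  chrs <- names(gm$chr_len)
  feasible <- gm$chr_len - len > 1
  if (!any(feasible))
    return(data.frame(chr = integer(), start = numeric(), end = numeric()))
  pr <- pmax(gm$chr_len - len, 0)
  out_chr <- integer(0); out_st <- numeric(0)
  for (t in seq_len(max_chunks)) {
    nb <- max(64L, 2L * (n - length(out_st)))
    cs <- sample(chrs[feasible], nb, replace = TRUE, prob = pr[feasible])
    uniform <- runif(nb) < 0.5
    st <- numeric(nb); k <- numeric(nb)
    for (ci in unique(cs)) {
      sel <- which(cs == ci)
      ps <- gm$positions[[ci]]
      u <- uniform[sel] | length(ps) == 0 | dens == 0
      s <- numeric(length(sel))
      s[u] <- floor(runif(sum(u), 1, gm$chr_len[[ci]] - len))
      if (any(!u)) {
        anchor <- ps[sample.int(length(ps), sum(!u), replace = TRUE)]
        s[!u] <- pmin(pmax(1, anchor - floor(runif(sum(!u), 0, len))),
                      floor(gm$chr_len[[ci]] - len))
      }
      st[sel] <- s
      k[sel] <- findInterval(s + len - 1, ps) - findInterval(s - 1, ps)
    }
    ok <- abs(k / len - dens) <= tol * dens | (dens == 0 & k == 0)
    out_chr <- c(out_chr, as.integer(cs[ok]))
    out_st <- c(out_st, st[ok])
    if (length(out_st) >= n) break
  }
  take <- seq_len(min(n, length(out_st)))
  data.frame(chr = out_chr[take], start = out_st[take],
             end = out_st[take] + len - 1)
}

# single matched placement (used by tests and single-shot callers)
.place_matched <- function(gm, len, dens, tol, max_tries = 100) {
  got <- .place_matched_batch(gm, len, dens, tol, n = 1,
                              max_chunks = ceiling(max_tries / 32))
  if (nrow(got) == 0) return(NULL)
  list(chr = got$chr[1], start = got$start[1], end = got$end[1])
}

# merged (disjoint, sorted) half-open member-gene intervals per
# chromosome, for O(log) region-stabbing overlap queries
.merged_gene_intervals <- function(genes, members, pad) {
  g <- genes[genes$gene %in% members, , drop = FALSE]
  if (nrow(g) == 0) return(list())
  g$start <- g$start - pad; g$end <- g$end + pad
  out <- list()
  for (c in unique(g$chr)) {
    gc <- g[g$chr == c, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    s <- gc$start[1]; e <- gc$end[1]; ms <- c(); me <- c()
    for (i in seq_len(nrow(gc))[-1]) {
      if (gc$start[i] <= e) e <- max(e, gc$end[i])
      else { ms <- c(ms, s); me <- c(me, e); s <- gc$start[i]; e <- gc$end[i] }
    }
    out[[as.character(c)]] <- list(s = c(ms, s), e = c(me, e))
  }
  out
}

# does each region [start, end] (1-based inclusive, compared half-open
# as [start, end+1)) overlap any merged member interval?
.regions_hit <- function(chr, start, end, merged) {
  hit <- logical(length(chr))
  for (c in unique(chr)) {
    mi <- merged[[as.character(c)]]
    if (is.null(mi)) next
    sel <- which(chr == c)
    idx <- findInterval(end[sel] + 1 - 1e-9, mi$s)
    hit[sel] <- idx >= 1 & mi$e[pmax(idx, 1)] > start[sel]
  }
  hit
}

#' Matched-permutation gene-set enrichment test
#'
#' The observed statistic of a gene set is the number of LD intervals
#' overlapping at least one member gene. Each of `R` null replicates
#' places one random region per observed interval, matched to it in
#' length and SNP density within `tol` (relative), uniformly among
#' feasible placements; the replicate statistic is computed identically,
#' and the empirical p is `(1 + #{replicate >= observed}) / (R + 1)`.
#' When no matched placement is found within a bounded number of draws
#' the tolerance for that interval is relaxed stepwise (x1.5) with a
#' warning.
#'
#' @param intervals data.frame from [build_ld_intervals()]
#' @param gene_sets long-format data.frame with columns `set`, `gene`
#' @param genes gene coordinates (columns `chr`, `start`, `end`, `gene`)
#' @param gm a [genome_model()]
#' @param R number of null replicates (default 50000; must be >= 1)
#' @param tol relative matching tolerance for length and density (0.1)
#' @param pad_bp gene padding passed to the overlap rule
#' @param seed integer seed
#' @return data.frame per gene set: `set`, `observed`, `empirical_p`,
#'   `genes` (comma-joined member genes overlapping any interval)
#' @export
enrichment_test <- function(intervals, gene_sets, genes, gm, R = 50000,
                            tol = 0.1, pad_bp = 0, seed = 1) {
  if (R < 1) stop("R must be >= 1: empirical p undefined without replicates")
  set.seed(seed)
  sets <- split(gene_sets$gene, gene_sets$set)
  ov <- map_intervals_to_genes(intervals, genes, pad_bp)
  obs <- vapply(sets, function(g) length(unique(ov$interval[ov$gene %in% g])),
                integer(1))
  contributing <- vapply(sets, function(g)
    paste(sort(intersect(unique(ov$gene), g)), collapse = ","), character(1))
  n_iv <- nrow(intervals)
  # R matched placements per template interval, shared by all sets;
  # replicate r uses the r-th placement of every interval
  placements <- vector("list", n_iv)
  for (i in seq_len(n_iv)) {
    tl <- tol
    repeat {
      got <- .place_matched_batch(gm, intervals$length[i],
                                  intervals$snp_density[i], tl, n = R)
      if (nrow(got) >= R) break
      tl <- tl * 1.5
      warning("relaxing matching tolerance to ", tl, " for interval ", i,
              call. = FALSE)
      if (tl > 100) stop("no feasible matched placement for interval ", i)
    }
    placements[[i]] <- got
  }
  exceed <- setNames(integer(length(sets)), names(sets))
  strict <- setNames(integer(length(sets)), names(sets))
  for (s in names(sets)) {
    merged <- .merged_gene_intervals(genes, sets[[s]], pad_bp)
    stat <- integer(R)
    for (i in seq_len(n_iv))
      stat <- stat + .regions_hit(placements[[i]]$chr, placements[[i]]$start,
                                  placements[[i]]$end, merged)
    exceed[[s]] <- sum(stat >= obs[[s]])
    strict[[s]] <- sum(stat > obs[[s]])
  }
  # n_ge / n_gt are reported so tie-aware rank conventions remain
  # recoverable from the output (the overlap count is discrete)
  data.frame(set = names(sets), observed = as.integer(obs),
             empirical_p = (1 + exceed) / (R + 1),
             n_ge = as.integer(exceed), n_gt = as.integer(strict),
             n_reps = as.integer(R),
             genes = contributing, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assemble the target gene list from several enrichment runs
#'
#' From each run (e.g. the four combinations of two association scans and
#' two gene-set collections), the `top_n` sets are taken ranked by
#' ascending empirical p (ties by descending observed overlap count, then
#' set name); their member genes that overlap any interval of that run
#' are collected, and the union over runs is returned deduplicated and
#' sorted.
#'
#' @param runs list of data.frames from [enrichment_test()]
#' @param top_n sets taken per run (default 20)
#' @return sorted character vector of target gene names
#' @export
assemble_target_genes <- function(runs, top_n = 20) {
  if (!length(runs)) stop("at least one enrichment run is required")
  genes <- character()
  for (run in runs) {
    ord <- order(run$empirical_p, -run$observed, run$set)
    top <- run[ord, , drop = FALSE][seq_len(min(top_n, nrow(run))), ]
    gl <- unlist(strsplit(top$genes[nzchar(top$genes)], ","))
    genes <- c(genes, gl)
  }
  sort(unique(genes))
}
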