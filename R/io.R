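#' Write a cohort as PLINK text files (.ped/.map)
#'
#' Genotypes are written as allele pairs; missing calls as `0 0`
#' (PLINK convention). Unknown parents are `0`.
#'
#' @param cohort a [pedigree_cohort()]
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are written
#' @return the prefix, invisibly
#' @export
write_plink_text <- function(cohort, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  map <- cohort$map
  write.table(map[, c("chr", "snp", "cm", "pos")],
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  G <- cohort$geno
  m <- ncol(G)
  a1 <- map$a1; a2 <- map$a2
  lines <- character(nrow(G))
  for (i in seq_len(nrow(G))) {
    g <- G[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    p <- cohort$ped[i, ]
    lines[i] <- paste(c(p$fid, p$iid, p$pid, p$mid, p$sex, p$aff,
                        as.vector(rbind(first, second))), collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK text files (.ped/.map) into a cohort
#'
#' Allele labels are taken from the data; at monomorphic markers the
#' unobserved allele is coded `"0"`. `a1` is the first allele seen.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`
#' @param a1,a2 optional character vectors fixing the allele labels per
#'   marker (recommended when round-tripping, so dosage orientation is
#'   preserved regardless of observed allele order)
#' @return a [pedigree_cohort()]
#' @export
read_plink_text <- function(prefix, a1 = NULL, a2 = NULL) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  for (f in c(mapf, pedf)) if (!file.exists(f)) stop("file not found: ", f)
  map <- read.table(mapf, col.names = c("chr", "snp", "cm", "pos"),
                    colClasses = c("integer", "character", "numeric", "integer"))
  toks <- strsplit(readLines(pedf), "[ \t]+")
  n <- length(toks); m <- nrow(map)
  ped <- data.frame(fid = character(n), iid = character(n),
                    pid = character(n), mid = character(n),
                    sex = integer(n), aff = integer(n),
                    stringsAsFactors = FALSE)
  A <- matrix("0", n, m); B <- matrix("0", n, m)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * m)
      stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tk))
    ped[i, 1:4] <- tk[1:4]
    ped$sex[i] <- as.integer(tk[5]); ped$aff[i] <- as.integer(tk[6])
    al <- tk[-(1:6)]
    A[i, ] <- al[seq(1, 2 * m, 2)]; B[i, ] <- al[seq(2, 2 * m, 2)]
  }
  if (is.null(a1)) {
    a1 <- character(m); a2 <- character(m)
    for (j in seq_len(m)) {
      obs <- setdiff(unique(c(A[, j], B[, j])), "0")
      a1[j] <- if (length(obs) >= 1) obs[1] else "0"
      a2[j] <- if (length(obs) >= 2) obs[2] else "0"
    }
  }
  G <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    miss <- A[, j] == "0" | B[, j] == "0"
    G[, j] <- (A[, j] == a1[j]) + (B[, j] == a1[j])
    G[miss, j] <- NA_integer_
  }
  map$a1 <- a1; map$a2 <- a2
  pedigree_cohort(ped, G, map)
}

#' Write a cohort as PLINK binary files (.bed/.bim/.fam)
#'
#' SNP-major .bed with magic bytes `0x6c 0x1b 0x01`; 2-bit codes
#' 00 = hom allele1, 10 = het, 11 = hom allele2, 01 = missing.
#'
#' @param cohort a [pedigree_cohort()]
#' @param prefix path prefix
#' @return the prefix, invisibly
#' @export
write_plink_binary <- function(cohort, prefix) {
  map <- cohort$map
  write.table(data.frame(map$chr, map$snp, map$cm, map$pos, map$a1, map$a2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cohort$ped[, c("fid", "iid", "pid", "mid", "sex", "aff")],
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  G <- cohort$geno
  n <- nrow(G); m <- ncol(G)
  # dosage of allele1 -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(3L, n, m)
  code[!is.na(G) & G == 2] <- 0L
  code[!is.na(G) & G == 1] <- 2L
  code[is.na(G)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, pad))
    dim(cj) <- c(4, bytes_per_snp)
    byte <- cj[1, ] + cj[2, ] * 4L + cj[3, ] * 16L + cj[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read PLINK binary files (.bed/.bim/.fam) into a cohort
#'
#' @param prefix path prefix
#' @return a [pedigree_cohort()]
#' @export
read_plink_binary <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("file not found: ", paste0(prefix, ext))
  bim <- read.table(paste0(prefix, ".bim"),
                    col.names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "iid", "pid", "mid", "sex", "aff"),
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "integer"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b || raw[3] != 0x01)
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4 * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  G <- matrix(NA_integer_, n, m)
  G[codes == 0L] <- 2L
  G[codes == 2L] <- 1L
  G[codes == 3L] <- 0L
  pedigree_cohort(fam, G, bim)
}

#' Read gene coordinates from a BED file
#'
#' Standard BED dialect: 0-based half-open, columns chrom, start, end,
#' name. A leading `chr` prefix on the chromosome is tolerated.
#'
#' @param path BED file path
#' @return data.frame with columns `chr` (integer), `start`, `end`, `gene`
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tk <- strsplit(lines[i], "\t")[[1]]
    if (length(tk) < 4)
      stop("malformed BED line ", i, ": fewer than 4 tab-separated fields")
    chr <- suppressWarnings(as.integer(sub("^chr", "", tk[1])))
    st <- suppressWarnings(as.integer(tk[2]))
    en <- suppressWarnings(as.integer(tk[3]))
    if (is.na(chr) || is.na(st) || is.na(en) || en < st)
      stop("malformed BED line ", i, ": bad coordinates")
    rows[[i]] <- data.frame(chr = chr, start = st, end = en, gene = tk[4],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$chr, out$start), , drop = FALSE]
}

#' Write gene coordinates as BED (0-based half-open)
#' @param genes data.frame with `chr`, `start`, `end`, `gene`
#' @param path output path
#' @return the path, invisibly
#' @export
write_gene_bed <- function(genes, path) {
  write.table(genes[, c("chr", "start", "end", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT format: one set per line — name, description, then tab-separated
#' member gene names.
#'
#' @param path GMT file path
#' @param source source label recorded for every set ("GO", "KEGG", ...)
#' @return data.frame with columns `set`, `source`, `gene` (long format,
#'   duplicate members dropped)
#' @export
read_gmt <- function(path, source = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    tk <- strsplit(lines[i], "\t")[[1]]
    if (length(tk) < 3) stop("malformed GMT line ", i, ": needs name, description, >=1 gene")
    data.frame(set = tk[1], source = source, gene = unique(tk[-(1:2)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a gene-set collection as GMT
#' @param sets data.frame with columns `set`, `gene` (long format)
#' @param path output path
#' @return the path, invisibly
#' @export
write_gmt <- function(sets, path) {
  by_set <- split(sets$gene, sets$set)
  lines <- vapply(names(by_set), function(s)
    paste(c(s, "na", unique(by_set[[s]])), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an eQTL catalogue TSV
#'
#' Expected header columns: `snp`, `gene`, `effect_allele`, `beta`, `p`,
#' `tissue`, and optionally `fdr`.
#'
#' @param path TSV path
#' @return data.frame of eQTL records
#' @export
read_eqtl_catalogue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp", "gene", "effect_allele", "beta", "p", "tissue")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("eQTL catalogue missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Write the complete synthetic dataset to a directory
#'
#' Emits every input the downstream pipeline consumes: PLINK text and
#' binary genotypes, gene coordinates (BED), gene sets (GMT), eQTL
#' catalogue (TSV) and the expression matrix with its probe map (TSV).
#'
#' @param dir output directory (created if absent)
#' @param cohort a [pedigree_cohort()]
#' @param catalogue eQTL record data.frame (optional)
#' @param expression result of [simulate_expression_matrix()] (optional)
#' @param genes gene BED data.frame (optional)
#' @param gene_sets gene-set data.frame (optional)
#' @return named character vector of written paths, invisibly
#' @export
write_dataset <- function(dir, cohort, catalogue = NULL, expression = NULL,
                          genes = NULL, gene_sets = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c()
  prefix <- file.path(dir, "cohort")
  write_plink_text(cohort, prefix)
  write_plink_binary(cohort, prefix)
  paths <- c(paths, ped = paste0(prefix, ".ped"), bed = paste0(prefix, ".bed"))
  if (!is.null(catalogue)) {
    p <- file.path(dir, "eqtl_catalogue.tsv")
    write.table(catalogue, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, catalogue = p)
  }
  if (!is.null(expression)) {
    p <- file.path(dir, "expression.tsv")
    write.table(data.frame(probe = rownames(expression$expr),
                           expression$expr, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- file.path(dir, "probe_map.tsv")
    write.table(expression$probe_map, pm, sep = "\t", quote = FALSE,
                row.names = FALSE)
    pg <- file.path(dir, "groups.tsv")
    write.table(data.frame(sample = names(expression$groups),
                           group = unname(expression$groups)),
                pg, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, expression = p, probe_map = pm, groups = pg)
  }
  if (!is.null(genes)) {
    p <- file.path(dir, "genes.bed")
    write_gene_bed(genes, p)
    paths <- c(paths, genes = p)
  }
  if (!is.null(gene_sets)) {
    p <- file.path(dir, "gene_sets.gmt")
    write_gmt(gene_sets, p)
    paths <- c(paths, gene_sets = p)
  }
  invisible(paths)
}
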