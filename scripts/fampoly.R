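#!/usr/bin/env Rscript
# Thin command-line dispatcher over the fampoly package:
#
#   Rscript scripts/fampoly.R simulate --out <dir> --seed <int>
#       [--families N] [--markers N] [--cases N] [--controls N]
#   Rscript scripts/fampoly.R qc --geno <prefix> --out <dir>
#   Rscript scripts/fampoly.R assoc --method dfam|emmax --geno <prefix> --out <dir>
#   Rscript scripts/fampoly.R de --expr <tsv> --groups <tsv> --map <tsv>
#       --targets <txt> --out <dir>
#   Rscript scripts/fampoly.R eqtl --catalogue <tsv> --dialect muther|blood
#       --geno <prefix> --targets <txt> --de-genes <txt> --out <dir>
#       [--nulls 500] [--seed N]

suppressMessages(library(fampoly))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1)
  stop("usage: fampoly.R <simulate|qc|assoc|de|eqtl> [options]")
cmd <- argv[1]
opts <- list()
i <- 2
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  opts[[key]] <- argv[i + 1]
  i <- i + 2
}
getopt <- function(name, default = NULL) {
  if (!is.null(opts[[name]])) opts[[name]] else
    if (!is.null(default)) default else stop("missing --", name)
}
num <- function(x) as.numeric(x)

if (cmd == "simulate") {
  out <- getopt("out")
  spec <- cohort_spec(n_families = num(getopt("families", 300)),
                      n_unrelated_cases = num(getopt("cases", 200)),
                      n_unrelated_controls = num(getopt("controls", 200)),
                      n_markers = num(getopt("markers", 1000)),
                      seed = num(getopt("seed", 1)))
  co <- simulate_cohort(spec)
  cata <- simulate_eqtl_catalogue(
    eqtl_catalogue_spec(seed = num(getopt("seed", 1))), co)
  expr <- simulate_expression_matrix(
    expression_spec(seed = num(getopt("seed", 1))))
  genes <- simulate_genes(co, seed = num(getopt("seed", 1)))
  sets <- simulate_gene_sets(genes$gene, seed = num(getopt("seed", 1)))
  write_dataset(out, co, catalogue = cata, expression = expr,
                genes = genes, gene_sets = sets)
  cat("dataset written to", out, "\n")

} else if (cmd == "qc") {
  co <- read_plink_binary(getopt("geno"))
  out <- getopt("out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  q <- run_qc(co)
  writeLines(q$cohort$ped$iid, file.path(out, "keep_samples.txt"))
  writeLines(q$cohort$map$snp, file.path(out, "keep_markers.txt"))
  writeLines(q$pruned, file.path(out, "pruned_markers.txt"))
  cat("retained", n_samples(q$cohort), "samples and",
      n_markers(q$cohort), "markers\n")

} else if (cmd == "assoc") {
  co <- read_plink_binary(getopt("geno"))
  out <- getopt("out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  method <- getopt("method", "dfam")
  res <- if (method == "dfam") dfam_scan(co) else emmax_scan(co)
  write.table(res, file.path(out, paste0(method, "_results.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(manhattan_coords(res),
              file.path(out, paste0(method, "_manhattan.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(method, "scan over", nrow(res), "markers written to", out, "\n")

} else if (cmd == "de") {
  expr_df <- read.table(getopt("expr"), header = TRUE, sep = "\t",
                        check.names = FALSE)
  expr <- as.matrix(expr_df[, -1])
  rownames(expr) <- expr_df[[1]]
  gr <- read.table(getopt("groups"), header = TRUE, sep = "\t")
  groups <- setNames(gr$group, gr$sample)
  pm <- read.table(getopt("map"), header = TRUE, sep = "\t")
  targets <- readLines(getopt("targets"))
  out <- getopt("out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  de <- differential_expression(expr, groups)
  ov <- overlap_with_targets(de, pm, targets)
  write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ov, file.path(out, "target_overlap.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sum(de$adj_p < 0.05), "significant probes;", nrow(ov),
      "target genes overlap\n")

} else if (cmd == "eqtl") {
  co <- read_plink_binary(getopt("geno"))
  cata <- read_eqtl_catalogue(getopt("catalogue"))
  targets <- readLines(getopt("targets"))
  de_genes <- if (!is.null(opts[["de-genes"]]))
    readLines(opts[["de-genes"]]) else character()
  rec <- if (getopt("dialect", "blood") == "blood")
    filter_blood(cata) else filter_muther(cata)
  out <- getopt("out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- eqtl_enrichment_scan(targets, rec, co, de_genes = de_genes,
                              N = num(getopt("nulls", 500)),
                              seed = num(getopt("seed", 1)))
  write.table(res, file.path(out, "eqtl_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("directed enrichment for", nrow(res), "genes written to", out, "\n")

} else stop("unknown subcommand: ", cmd)
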