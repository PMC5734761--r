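#' Published directed-eQTL summary tables
#'
#' Per-gene summary rows of the published directed eQTL enrichment in the
#' nasal-polyposis case/control cohort, one table per eQTL catalogue
#' (whole-blood and multi-tissue). Each row carries the gene name, the
#' published two-sided Fisher p, the published empirical p, the log2 fold
#' change from the expression comparison, the number of eQTL SNPs and the
#' four directed contingency cells (Up+/Up-/Down+/Down-). The cells are
#' inputs from which the Fisher p can be recomputed end-to-end, which is
#' how the package validates its binning schema and exact test.
#'
#' @param catalogue `"blood"` or `"multitissue"`
#' @return data.frame with columns `gene`, `fisher_p`, `empirical_p`,
#'   `log2fc`, `n_snps`, `up_plus`, `up_minus`, `down_plus`, `down_minus`
#' @export
published_eqtl_summary <- function(catalogue = c("blood", "multitissue")) {
  catalogue <- match.arg(catalogue)
  path <- system.file("extdata",
                      paste0("eqtl_enrichment_", catalogue, ".tsv"),
                      package = "fampoly", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
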