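#' Two-group differential expression (Welch t-test)
#'
#' Per probe, a Welch two-sample t-test on log2-scale intensities and
#' `log2FC = mean(case) - mean(control)`. Degenerate probes: both groups
#' with zero variance and equal means get p = 1; zero variance with
#' unequal means gets p = 0 and is flagged.
#'
#' @param expr matrix, probes x samples (log2 scale)
#' @param groups character vector or factor over samples with levels
#'   "case" and "control" (named vectors are matched to column names)
#' @return data.frame per probe: `probe`, `log2fc`, `p`, `adj_p`
#'   (Benjamini-Hochberg), `degenerate`
#' @export
differential_expression <- function(expr, groups) {
  if (!is.null(names(groups)) && !is.null(colnames(expr)))
    groups <- groups[colnames(expr)]
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  ca <- expr[, groups == "case", drop = FALSE]
  co <- expr[, groups == "control", drop = FALSE]
  if (ncol(ca) < 2 || ncol(co) < 2) stop("need >= 2 samples per group")
  np <- nrow(expr)
  p <- numeric(np); lfc <- numeric(np); degen <- logical(np)
  for (i in seq_len(np)) {
    x <- ca[i, ]; y <- co[i, ]
    lfc[i] <- mean(x) - mean(y)
    if (var(x) == 0 && var(y) == 0) {
      degen[i] <- TRUE
      p[i] <- if (lfc[i] == 0) 1 else 0
    } else {
      p[i] <- t.test(x, y)$p.value
    }
  }
  data.frame(probe = rownames(expr), log2fc = lfc, p = p,
             adj_p = bh_adjust(p), degenerate = degen,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up rule
#' (`adj_i = min over j >= i of m p_(j) / j`, capped at 1, restored to
#' input order).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no NA")
  p.adjust(p, method = "BH")
}

#' Intersect differential-expression results with a target gene list
#'
#' Reports the target genes having at least one probe with adjusted
#' p below `fdr`; per gene the most significant probe's adjusted p and
#' log2 fold change are reported together with the fold change
#' `2^log2FC`.
#'
#' @param de result of [differential_expression()]
#' @param probe_map data.frame with columns `probe`, `gene`
#' @param targets character vector of target gene names
#' @param fdr adjusted-p cutoff (default 0.05, strict `<`)
#' @return data.frame per significant target gene: `gene`, `probe`,
#'   `adj_p`, `log2fc`, `fc`, ordered by descending log2fc
#' @export
overlap_with_targets <- function(de, probe_map, targets, fdr = 0.05) {
  de <- merge(de, probe_map, by = "probe")
  de <- de[de$gene %in% targets, , drop = FALSE]
  rows <- lapply(split(de, de$gene), function(d) {
    d <- d[order(d$adj_p), , drop = FALSE][1, ]
    if (d$adj_p < fdr) d else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene = character(), probe = character(),
                      adj_p = numeric(), log2fc = numeric(), fc = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- data.frame(gene = out$gene, probe = out$probe, adj_p = out$adj_p,
                    log2fc = out$log2fc, fc = 2^out$log2fc,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$log2fc), , drop = FALSE]
}
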