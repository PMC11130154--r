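## Marker-based CAF-S1/CAF-S5 filtering of single-cell expression matrices
## and rank-based two-group differential expression.

#' Default protein-to-gene alias map
#'
#' Subset definitions use protein names; expression matrices use gene
#' symbols. CD29 maps to ITGB1, FSP1 to S100A4 and alpha-SMA to ACTA2.
#'
#' @return Named character vector, protein name -> gene symbol.
#' @export
caf_gene_aliases <- function() {
  c(CD29 = "ITGB1", PDGFRb = "PDGFRB", PDPN = "PDPN", FAP = "FAP",
    FSP1 = "S100A4", aSMA = "ACTA2")
}

#' Filter fibroblasts to CAF-S1 / CAF-S5 by marker expression
#'
#' A cell is retained iff it expresses (count > 0) all of ITGB1 (CD29),
#' PDGFRB, PDPN and FAP and does not express S100A4 (FSP1). Retained cells
#' are CAF-S1 if they express ACTA2 (alpha-SMA) and CAF-S5 if they do not.
#' All other cells are `"excluded"`. The operation is deterministic and
#' idempotent.
#'
#' @param counts Genes x cells matrix of non-negative counts with gene
#'   symbols as row names.
#' @param aliases Protein-to-symbol map, as [caf_gene_aliases()].
#' @return Character vector (one per cell) in
#'   `{"CAF-S1", "CAF-S5", "excluded"}`.
#' @export
filter_caf_s1_s5 <- function(counts, aliases = caf_gene_aliases()) {
  need <- unname(aliases[c("CD29", "PDGFRb", "PDPN", "FAP", "FSP1", "aSMA")])
  missing_g <- setdiff(need, rownames(counts))
  if (length(missing_g)) {
    stop("required gene(s) absent from matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(counts)
  incl <- counts[aliases[["CD29"]], ] > 0 &
    counts[aliases[["PDGFRb"]], ] > 0 &
    counts["PDPN", ] > 0 &
    counts["FAP", ] > 0 &
    counts[aliases[["FSP1"]], ] == 0
  out <- rep("excluded", ncol(counts))
  out[incl & counts[aliases[["aSMA"]], ] > 0] <- "CAF-S1"
  out[incl & counts[aliases[["aSMA"]], ] == 0] <- "CAF-S5"
  out
}

cpm_log <- function(counts, scale = 1e6) {
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  log1p(sweep(counts, 2, libsize, "/") * scale)
}

#' Two-group differential expression (CAF-S5 vs CAF-S1)
#'
#' Per-gene two-sided Wilcoxon rank-sum test on library-size-normalised
#' log counts (counts-per-million, log1p), with Benjamini-Hochberg
#' correction across tested genes. Genes expressed in fewer than
#' `min_cells` cells overall are not tested. The log2 fold-change is the
#' difference of group means of `log2(CPM + 1)`, positive when the gene is
#' up in CAF-S5.
#'
#' @param counts Genes x cells count matrix (symbols as row names).
#' @param labels Per-cell labels; only `"CAF-S1"` and `"CAF-S5"` cells enter
#'   the test (others are dropped), and both groups need >= 3 cells.
#' @param min_cells Minimum number of expressing cells for a gene to be
#'   tested (default 3).
#' @return Data frame of class `caf_de`: `gene`, `lfc`, `p`, `q`,
#'   `mean_s1`, `mean_s5` (mean CPM per group); untested genes carry NA
#'   p/q.
#' @export
differential_expression <- function(counts, labels, min_cells = 3) {
  stopifnot(ncol(counts) == length(labels))
  keep <- labels %in% c("CAF-S1", "CAF-S5")
  counts <- as.matrix(counts[, keep, drop = FALSE])
  labels <- labels[keep]
  n1 <- sum(labels == "CAF-S1"); n5 <- sum(labels == "CAF-S5")
  if (n1 < 3 || n5 < 3) {
    stop("both groups need at least 3 cells (got ", n1, " and ", n5, ")",
         call. = FALSE)
  }
  norm <- cpm_log(counts)
  l2 <- norm / log(2)
  g1 <- labels == "CAF-S1"
  g5 <- labels == "CAF-S5"

  expressed <- rowSums(counts > 0)
  testable <- expressed >= min_cells
  p <- rep(NA_real_, nrow(counts))
  for (i in which(testable)) {
    a <- l2[i, g5]; b <- l2[i, g1]
    if (max(a, b) == min(a, b)) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(
        wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    }
  }
  q <- rep(NA_real_, length(p))
  q[testable] <- p.adjust(p[testable], method = "BH")

  cpm <- expm1(norm)
  out <- data.frame(
    gene = rownames(counts),
    lfc = rowMeans(l2[, g5, drop = FALSE]) - rowMeans(l2[, g1, drop = FALSE]),
    p = p, q = q,
    mean_s1 = rowMeans(cpm[, g1, drop = FALSE]),
    mean_s5 = rowMeans(cpm[, g5, drop = FALSE]),
    row.names = NULL)
  class(out) <- c("caf_de", "data.frame")
  out
}

#' Top differentially expressed genes
#'
#' Orders tested genes by adjusted p value, breaking ties by absolute log2
#' fold-change (descending) and then gene symbol, and returns the first
#' `n`.
#'
#' @param de A `caf_de` result.
#' @param n Number of genes to return (default 50; clipped to the number of
#'   tested genes).
#' @return Character vector of gene symbols.
#' @export
top_genes <- function(de, n = 50) {
  if (!nrow(de)) stop("empty DE result", call. = FALSE)
  de <- de[!is.na(de$q), , drop = FALSE]
  ord <- order(de$q, -abs(de$lfc), de$gene)
  de$gene[ord][seq_len(min(n, nrow(de)))]
}
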