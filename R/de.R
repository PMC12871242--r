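# Inside- vs outside-niche differential expression for one cell type:
# library-size normalization, per-gene two-sided Wilcoxon rank-sum test
# (normal approximation with tie and continuity correction), BH adjustment
# across the tested genes.

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to a common total (`target_sum`), then applies
#' `log1p`. Cells with zero total counts cannot be scaled and are dropped;
#' their ids are reported in the `dropped_cells` attribute. Proportional
#' count profiles normalize to identical values, and per-cell sums of
#' `expm1(normalized)` equal `target_sum`.
#'
#' @param counts Genes x cells sparse count matrix ([read_counts_mtx()]).
#' @param target_sum Per-cell total after scaling (default 10^4).
#' @return A `dgCMatrix` of log1p-normalized values with attribute
#'   `dropped_cells` (character vector of removed cell ids).
#' @export
normalize_counts <- function(counts, target_sum = 1e4) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  totals <- Matrix::colSums(counts)
  dropped <- colnames(counts)[totals == 0]
  if (length(dropped) == ncol(counts))
    abort_domain("all cells have zero total counts")
  keep <- totals > 0
  m <- counts[, keep, drop = FALSE]
  m <- m %*% Matrix::Diagonal(x = target_sum / totals[keep])
  m <- as(m, "CsparseMatrix")
  m@x <- log1p(m@x)
  dimnames(m) <- list(rownames(counts), colnames(counts)[keep])
  structure(m, dropped_cells = dropped)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order, `q >= p` elementwise, and `q <= 1`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) > 0 &&
      (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)))
    abort_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# two-sided rank-sum p; constant pooled sample has nothing to test -> p = 1
ranksum_p <- function(a, b) {
  if (max(c(a, b)) == min(c(a, b))) return(1)
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

#' Differential expression inside vs outside microniches
#'
#' Contrasts the cells of one type that belong to a detected niche against
#' the same type outside all niches. Counts are library-size normalized and
#' log-transformed ([normalize_counts()]); each gene is tested with a
#' two-sided Wilcoxon rank-sum test; q-values are BH-adjusted across the
#' tested genes only. Genes expressed in zero cells of both groups are
#' excluded before testing and counted in the `n_filtered` attribute. The
#' fold change is `log2((mean_in + pc) / (mean_out + pc))` on normalized
#' values, with a tiny pseudocount `pc` used for the ratio only (never the
#' test), so its sign always reflects the group means. Positive values mean
#' higher expression inside niches.
#'
#' @param cells `cell_tbl` the membership labels refer to.
#' @param counts Genes x cells count matrix; columns must cover the tested
#'   cells.
#' @param membership Per-cell labels from [assign_niche_membership()]
#'   (length `nrow(cells)`).
#' @param cell_type One of `DC`, `T_CONV`, `T_REG`, `OTHER`.
#' @param min_cells_per_group Minimum cells on each side (default 10; below
#'   this the rank-sum normal approximation is unreliable).
#' @param pseudocount Added to normalized means for the fold change only
#'   (default 1e-9).
#' @param target_sum Passed to [normalize_counts()].
#' @return A `de_table` data frame (`gene`, `n_inside`, `n_outside`,
#'   `log2_fold_change`, `p_value`, `q_value`) sorted by `q_value`, then
#'   decreasing `|log2_fold_change|`, then gene name; attribute `n_filtered`
#'   counts all-zero genes removed before testing.
#' @export
de_inside_outside <- function(cells, counts, membership, cell_type,
                              min_cells_per_group = 10L,
                              pseudocount = 1e-9, target_sum = 1e4) {
  if (!cell_type %in% CELL_TYPES)
    abort_validation(sprintf("unknown cell_type '%s'", cell_type))
  if (length(membership) != nrow(cells))
    abort_validation("membership must have one label per cell")
  sel <- cells$cell_type == cell_type
  inside_ids  <- cells$cell_id[sel & membership != "NONE"]
  outside_ids <- cells$cell_id[sel & membership == "NONE"]
  miss <- setdiff(c(inside_ids, outside_ids), colnames(counts))
  if (length(miss) > 0L)
    abort_validation(sprintf("count matrix lacks %d tested cell(s)",
                             length(miss)))
  norm <- normalize_counts(counts, target_sum)
  inside_ids  <- setdiff(inside_ids,  attr(norm, "dropped_cells"))
  outside_ids <- setdiff(outside_ids, attr(norm, "dropped_cells"))
  if (length(inside_ids) < min_cells_per_group)
    abort_domain(sprintf("inside group has %d cells (< %d required)",
                         length(inside_ids), min_cells_per_group))
  if (length(outside_ids) < min_cells_per_group)
    abort_domain(sprintf("outside group has %d cells (< %d required)",
                         length(outside_ids), min_cells_per_group))
  A <- as.matrix(norm[, inside_ids, drop = FALSE])
  B <- as.matrix(norm[, outside_ids, drop = FALSE])
  expressed <- rowSums(A) + rowSums(B) > 0
  n_filtered <- sum(!expressed)
  genes <- rownames(norm)[expressed]
  if (length(genes) == 0L) abort_domain("no expressed genes to test")
  A <- A[expressed, , drop = FALSE]
  B <- B[expressed, , drop = FALSE]
  p <- vapply(seq_along(genes), function(g) ranksum_p(A[g, ], B[g, ]),
              numeric(1))
  lfc <- log2((rowMeans(A) + pseudocount) / (rowMeans(B) + pseudocount))
  out <- data.frame(gene = genes,
                    n_inside = length(inside_ids),
                    n_outside = length(outside_ids),
                    log2_fold_change = unname(lfc),
                    p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, -abs(out$log2_fold_change), out$gene), ]
  rownames(out) <- NULL
  structure(out, n_filtered = n_filtered,
            class = c("de_table", "data.frame"))
}

#' Write a DE table as TSV
#'
#' Stable column order, floats at full precision.
#'
#' @param x A `de_table`.
#' @param path Output path.
#' @export
write_de_table <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("log2_fold_change", "p_value", "q_value"))
    df[[col]] <- fmt_num(df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
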