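# Clonal-architecture statistics: clone summaries, R20, expansion and
# Treg/Tconv sharing. One cell = one unit of repertoire mass throughout.

subject_rows <- function(rep, subject_id) {
  idx <- rep$subject_id == subject_id
  if (!any(idx))
    abort_domain(sprintf("subject '%s' not present in repertoire", subject_id))
  rep[idx, , drop = FALSE]
}

categorize_clone <- function(n_treg, n_tconv) {
  ifelse(n_treg >= 1L & n_tconv >= 1L, "SHARED",
         ifelse(n_tconv == 0L, "TREG_ONLY", "TCONV_ONLY"))
}

#' Summarize clones for one subject
#'
#' Groups one subject's cells by clonotype and returns one record per clone
#' with its size (in cells), lineage composition, and sharing category:
#' `SHARED` if the clone contains at least one Foxp3+ (Treg) and one Foxp3-
#' (Tconv) cell, otherwise `TREG_ONLY` / `TCONV_ONLY`. Clone counts partition
#' the subject's cells exactly.
#'
#' @param rep A `repertoire_tbl` (see [read_repertoire()]).
#' @param subject_id Subject to summarize; must be present.
#' @return Data frame with columns `clone_id`, `size`, `n_treg`, `n_tconv`,
#'   `category`, sorted by decreasing size then `clone_id`.
#' @export
summarize_clones <- function(rep, subject_id) {
  cells <- subject_rows(rep, subject_id)
  tab <- table(factor(cells$clone_id),
               factor(cells$lineage, levels = LINEAGES))
  out <- data.frame(clone_id = rownames(tab),
                    n_treg   = as.integer(tab[, "TREG"]),
                    n_tconv  = as.integer(tab[, "TCONV"]),
                    stringsAsFactors = FALSE)
  out$size <- out$n_treg + out$n_tconv
  out$category <- categorize_clone(out$n_treg, out$n_tconv)
  out <- out[order(-out$size, out$clone_id), c("clone_id", "size", "n_treg",
                                               "n_tconv", "category")]
  rownames(out) <- NULL
  out
}

#' R20 clonality score
#'
#' Fraction of unique clones, taken in descending order of size, needed to
#' account for 20% of the sequenced repertoire. Clones are ranked by cell
#' count; with `N` total cells and `C` unique clones, the score is `k / C`
#' where `k` is the smallest number of top clones whose cumulative cell count
#' reaches at least `fraction_threshold * N` (the threshold is inclusive).
#' Low values indicate oligoclonal expansion; a repertoire of `C` equal-sized
#' clones scores `ceiling(0.2 * C) / C`, so a fully polyclonal
#' (all-singleton) repertoire scores ~0.2 and a monoclonal one scores 1.
#'
#' The score depends only on the multiset of clone sizes, so it is invariant
#' to input order and clone relabeling; ties in size cannot change `k`.
#'
#' @param clone_sizes Integer vector of clone sizes (cells per clone), all
#'   >= 1.
#' @param fraction_threshold Repertoire fraction to cover (default 0.20).
#' @return The score, a fraction in (0, 1].
#' @export
r20_score <- function(clone_sizes, fraction_threshold = 0.20) {
  if (length(clone_sizes) == 0L) abort_domain("empty clone-size list")
  if (any(!is.finite(clone_sizes)) || any(clone_sizes < 1))
    abort_validation("all clone sizes must be >= 1")
  sizes <- sort(as.numeric(clone_sizes), decreasing = TRUE)
  thr <- fraction_threshold * sum(sizes)
  k <- which(cumsum(sizes) >= thr)[1L]
  k / length(sizes)
}

#' Fraction of expanded clones
#'
#' A clone is expanded when more than one cell carries the same clonotype.
#' Returns the number of expanded clones over the total clone count; 0 iff
#' the repertoire is fully polyclonal (all singletons).
#'
#' @param clones Clone summary from [summarize_clones()], or a numeric vector
#'   of clone sizes.
#' @return Fraction in \[0, 1\].
#' @export
expanded_fraction <- function(clones) {
  sizes <- if (is.data.frame(clones)) clones$size else as.numeric(clones)
  if (length(sizes) == 0L) abort_domain("empty clone list")
  mean(sizes > 1)
}

#' Composition of expanded clones by sharing category
#'
#' Among clones with more than one cell, the fraction falling in each sharing
#' category (`TREG_ONLY`, `TCONV_ONLY`, `SHARED`). Fractions sum to 1 when
#' any expanded clone exists; with none, an all-`NA` vector is returned with
#' attribute `no_expanded = TRUE` (an empty repertoire stratum, not an
#' error).
#'
#' @param clones Clone summary from [summarize_clones()].
#' @return Named numeric vector over the three categories, with attributes
#'   `n_expanded` and `no_expanded`.
#' @export
expanded_composition <- function(clones) {
  exp_cl <- clones[clones$size > 1L, , drop = FALSE]
  n_exp <- nrow(exp_cl)
  if (n_exp == 0L) {
    out <- stats::setNames(rep(NA_real_, length(CLONE_CATEGORIES)),
                           CLONE_CATEGORIES)
    return(structure(out, n_expanded = 0L, no_expanded = TRUE))
  }
  counts <- table(factor(exp_cl$category, levels = CLONE_CATEGORIES))
  structure(as.numeric(counts) / n_exp, names = CLONE_CATEGORIES,
            n_expanded = n_exp, no_expanded = FALSE)
}

#' Per-subject repertoire summary
#'
#' Assembles the clonality statistics for one subject: cell and clone counts,
#' R20 score, expanded-clone fraction, the category composition of expanded
#' clones, and the number of Treg/Tconv-shared clones. A monoclonal
#' repertoire (one clone) is flagged as degenerate: its R20 of 1.0 is the
#' literal value of the formula, not evidence of polyclonality.
#'
#' @inheritParams summarize_clones
#' @param fraction_threshold Passed to [r20_score()].
#' @return One-row data frame: `subject_id`, `timepoint`, `n_cells`,
#'   `n_clones`, `r20`, `monoclonal`, `expanded_fraction`,
#'   `expanded_frac_treg_only`, `expanded_frac_tconv_only`,
#'   `expanded_frac_shared`, `shared_clone_count`.
#' @export
summarize_subject <- function(rep, subject_id, fraction_threshold = 0.20) {
  cl <- summarize_clones(rep, subject_id)
  comp <- expanded_composition(cl)
  cells <- subject_rows(rep, subject_id)
  tp <- unique(cells$timepoint)
  data.frame(
    subject_id = subject_id,
    timepoint  = if (length(tp) == 1L) tp else NA_character_,
    n_cells    = sum(cl$size),
    n_clones   = nrow(cl),
    r20        = r20_score(cl$size, fraction_threshold),
    monoclonal = nrow(cl) == 1L,
    expanded_fraction = expanded_fraction(cl),
    expanded_frac_treg_only  = unname(comp["TREG_ONLY"]),
    expanded_frac_tconv_only = unname(comp["TCONV_ONLY"]),
    expanded_frac_shared     = unname(comp["SHARED"]),
    shared_clone_count = sum(cl$category == "SHARED"),
    stringsAsFactors = FALSE)
}

#' Summaries for all subjects in a table
#'
#' Applies [summarize_subject()] to every subject; each row depends only on
#' that subject's cells (no pooling across subjects).
#'
#' @inheritParams summarize_subject
#' @return Data frame, one row per subject, in order of first appearance.
#' @export
summarize_repertoire <- function(rep, fraction_threshold = 0.20) {
  subjects <- unique(rep$subject_id)
  out <- do.call(rbind, lapply(subjects, function(s)
    summarize_subject(rep, s, fraction_threshold)))
  rownames(out) <- NULL
  out
}

#' Subsampled clonality statistic with percentile interval
#'
#' Subjects differ in the number of sequenced cells, and both R20 and the
#' expanded fraction depend on sampling depth. This normalization layer
#' repeatedly subsamples a fixed number of cells without replacement,
#' recomputes the statistic on each subsample, and reports the bootstrap mean
#' with a 2.5-97.5 percentile interval, making subjects comparable at equal
#' depth.
#'
#' @inheritParams summarize_clones
#' @param statistic `"R20"` or `"EXPANDED_FRACTION"`.
#' @param n_cells_target Cells per subsample; must not exceed the subject's
#'   cell count (equal means a degenerate, zero-width interval at the
#'   full-sample value).
#' @param n_boot Number of subsamples (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param fraction_threshold Passed to [r20_score()] when relevant.
#' @return List with `mean`, `lower`, `upper` (2.5/97.5 percentiles), and the
#'   per-replicate `values`.
#' @export
subsample_statistic <- function(rep, subject_id,
                                statistic = c("R20", "EXPANDED_FRACTION"),
                                n_cells_target, n_boot = 200L, seed = 1L,
                                fraction_threshold = 0.20) {
  statistic <- match.arg(statistic)
  cells <- subject_rows(rep, subject_id)
  n <- nrow(cells)
  if (n_cells_target > n)
    abort_domain(sprintf(
      "n_cells_target (%d) exceeds subject cell count (%d)",
      n_cells_target, n))
  if (n_boot < 1L) abort_validation("n_boot must be >= 1")
  stat_fun <- switch(statistic,
    R20 = function(sizes) r20_score(sizes, fraction_threshold),
    EXPANDED_FRACTION = function(sizes) mean(sizes > 1))
  vals <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n_cells_target)
    stat_fun(as.numeric(table(cells$clone_id[idx])))
  }, numeric(1)))
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(mean = mean(vals), lower = qs[1L], upper = qs[2L], values = vals)
}
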