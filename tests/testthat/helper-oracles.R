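# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force cumulative sums, union-find
# clustering, all-pairs scans, shoelace and ray casting re-derivations.

# R20 by explicit cumulative scan over sizes sorted descending
brute_r20 <- function(sizes, threshold = 0.2) {
  s <- sort(sizes, decreasing = TRUE)
  need <- threshold * sum(s)
  acc <- 0
  for (k in seq_along(s)) {
    acc <- acc + s[k]
    if (acc >= need) return(k / length(s))
  }
  1
}

# random repertoire as a plain data frame convertible to repertoire_tbl
random_repertoire <- function(n_clones = 20, max_size = 10, p_treg = 0.4,
                              subject = "s1") {
  sizes <- sample.int(max_size, n_clones, replace = TRUE)
  df <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(sum(sizes))),
    subject_id = subject,
    timepoint = "t",
    clone_id = rep(sprintf("cl%03d", seq_len(n_clones)), sizes),
    lineage = ifelse(runif(sum(sizes)) < p_treg, "TREG", "TCONV"),
    stringsAsFactors = FALSE)
  structure(df, class = c("repertoire_tbl", "data.frame"), n_dropped = 0L)
}

# naive quadratic DBSCAN with the same deterministic tie rule:
# union-find over core-core pairs, canonical cluster ids by the minimal
# core point in (x, y, cell_id) order, border points to the nearest core
# (ties to the lower canonical id), then the same composition filter.
# Returns the set of member-id sets (sorted) for direct comparison.
reference_niche_sets <- function(cells, eps, min_samples, min_dc = 1,
                                 min_t = 1,
                                 included = c("DC", "T_CONV", "T_REG")) {
  df <- cells[cells$cell_type %in% included, , drop = FALSE]
  n <- nrow(df)
  if (n == 0) return(list())
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_samples,
                 logical(1))
  parent <- seq_len(n)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in which(core)) {
    if (i < j && D[i, j] <= eps) {
      ri <- find_root(i); rj <- find_root(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  comp <- rep(NA_integer_, n)
  core_idx <- which(core)
  if (length(core_idx) == 0) return(list())
  # canonical numbering: order components by their minimal core member
  key_ord <- core_idx[order(df$x[core_idx], df$y[core_idx],
                            df$cell_id[core_idx])]
  canon <- integer(0)
  for (i in key_ord) {
    r <- root[i]
    if (!as.character(r) %in% names(canon))
      canon[as.character(r)] <- length(canon) + 1L
  }
  comp[core_idx] <- canon[as.character(root[core_idx])]
  for (b in which(!core)) {
    nb <- core_idx[D[b, core_idx] <= eps]
    if (length(nb) == 0) next
    d <- D[b, nb]
    cand <- nb[d == min(d)]
    comp[b] <- min(canon[as.character(root[cand])])
  }
  sets <- list()
  for (k in sort(unique(stats::na.omit(comp)))) {
    idx <- which(comp == k)
    ndc <- sum(df$cell_type[idx] == "DC")
    nt <- sum(df$cell_type[idx] %in% c("T_CONV", "T_REG"))
    if (ndc >= min_dc && nt >= min_t)
      sets[[length(sets) + 1L]] <- sort(df$cell_id[idx])
  }
  sets
}

niche_member_sets <- function(niches) {
  lapply(niches, function(nn) sort(nn$member_cell_ids))
}

# canonicalize a list of sets for order-free comparison
sort_sets <- function(sets) {
  if (length(sets) == 0) return(sets)
  sets[order(vapply(sets, function(s) paste(s, collapse = "|"),
                    character(1)))]
}

random_cell_table <- function(n, field = 500, p_types = c(DC = 0.2,
                                                          T_CONV = 0.4,
                                                          T_REG = 0.2,
                                                          OTHER = 0.2)) {
  structure(data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    x = runif(n, 0, field), y = runif(n, 0, field),
    cell_type = sample(names(p_types), n, replace = TRUE, prob = p_types),
    stringsAsFactors = FALSE),
    class = c("cell_tbl", "data.frame"), n_unknown_type = 0L)
}

# all-pairs nearest-DC scan
brute_nearest_dc <- function(cells) {
  t_idx <- which(cells$cell_type %in% c("T_CONV", "T_REG"))
  d_idx <- which(cells$cell_type == "DC")
  vapply(t_idx, function(i)
    min(sqrt((cells$x[i] - cells$x[d_idx])^2 +
               (cells$y[i] - cells$y[d_idx])^2)), numeric(1))
}

# shoelace over an explicit vertex walk
shoelace <- function(xs, ys) {
  n <- length(xs)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xs[i] * ys[j] - xs[j] * ys[i]
  }
  abs(s) / 2
}

# ray casting re-derivation (horizontal ray to +Inf, crossing count)
ray_cast_inside <- function(px, py, xs, ys) {
  n <- length(xs)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if ((ys[i] <= py && ys[j] > py) || (ys[j] <= py && ys[i] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (xint > px) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}
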