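# Microniche detection and whole-slide spatial statistics.
#
# Clustering follows DBSCAN semantics (core point: >= min_samples points
# within eps, counting itself; clusters: connected components of core points
# plus reachable border points) but pins down the one order-dependent choice
# classic DBSCAN leaves open: a border point reachable from several clusters
# goes to the cluster of its nearest core point, ties to the lower canonical
# cluster id. Canonical cluster ids are assigned by scanning core points in
# (x, y, cell_id) order, so the output is invariant to input row order.

#' Microniche detection parameters
#'
#' @param eps Neighborhood radius in micrometers (> 0). Default 30, on the
#'   order of 2-3 hepatocyte diameters.
#' @param min_samples Core-point threshold, counting the point itself
#'   (>= 2). Default 5, the conventional 2*dim + 1 heuristic for planar
#'   points.
#' @param min_dc Minimum dendritic cells for a cluster to count as a DC-T
#'   microniche (>= 1).
#' @param min_t Minimum T cells (conventional + regulatory) per niche
#'   (>= 1). Default 3 so pure-DC or DC-plus-one-T contacts are not called
#'   niches.
#' @param included_types Cell types entering the clustering; others are
#'   ignored entirely (they can lie inside a niche's hull without being
#'   members).
#' @return A validated `niche_params` list.
#' @export
niche_params <- function(eps = 30, min_samples = 5L, min_dc = 1L, min_t = 3L,
                         included_types = c("DC", "T_CONV", "T_REG")) {
  if (!is.finite(eps) || eps <= 0) abort_validation("eps must be > 0")
  if (min_samples < 2L) abort_validation("min_samples must be >= 2")
  if (min_dc < 1L) abort_validation("min_dc must be >= 1")
  if (min_t < 1L) abort_validation("min_t must be >= 1")
  if (!all(included_types %in% CELL_TYPES))
    abort_validation("included_types must be drawn from the cell-type enum")
  structure(list(eps = eps, min_samples = as.integer(min_samples),
                 min_dc = as.integer(min_dc), min_t = as.integer(min_t),
                 included_types = included_types),
            class = "niche_params")
}

# hull area in um^2; NA (flagged) for collinear member sets
hull_area <- function(xy) {
  if (nrow(xy) < 3L) return(NA_real_)
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(NA_real_)
  a <- polygon_area(xy[h, , drop = FALSE])
  if (a <= 0) NA_real_ else a
}

new_niche <- function(id, members, xy, types) {
  comp <- table(factor(types, levels = CELL_TYPES))
  structure(list(
    niche_id = id,
    member_cell_ids = members,
    centroid = c(x = mean(xy[, 1L]), y = mean(xy[, 2L])),
    composition = stats::setNames(as.integer(comp), CELL_TYPES),
    area_proxy = hull_area(xy),
    is_parenchymal = NA), class = "niche")
}

#' Detect DC-T cell microniches by density-based clustering
#'
#' Runs deterministic DBSCAN (see above) on the cells of
#' `params$included_types`, discards noise, and keeps clusters satisfying the
#' composition rule (at least `min_dc` dendritic cells and `min_t` T cells).
#' Niches are returned sorted by decreasing member count, ties broken by
#' centroid x then y, and re-numbered 1..k in that order. The result is
#' invariant to permutations of the input rows and to rigid motions of the
#' coordinates (up to the centroid values themselves).
#'
#' @param cells A `cell_tbl` ([read_cell_table()]).
#' @param params A [niche_params()] object.
#' @return A `niche_list`: list of `niche` objects (`niche_id`,
#'   `member_cell_ids`, `centroid`, `composition`, `area_proxy`,
#'   `is_parenchymal`, initially `NA`). Empty input gives an empty list.
#' @export
detect_microclusters <- function(cells, params = niche_params()) {
  stopifnot(inherits(params, "niche_params"))
  sub <- cells[cells$cell_type %in% params$included_types, , drop = FALSE]
  n <- nrow(sub)
  empty <- structure(list(), class = "niche_list")
  if (n == 0L) return(empty)

  # canonical processing order: coordinates then id, never row index
  ord <- order(sub$x, sub$y, sub$cell_id)
  sub <- sub[ord, , drop = FALSE]
  xy <- cbind(sub$x, sub$y)
  D <- as.matrix(stats::dist(xy))
  nbr <- D <= params$eps
  is_core <- rowSums(nbr) >= params$min_samples

  comp_id <- integer(n)                       # 0 = unassigned / noise
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || comp_id[i] != 0L) next
    next_id <- next_id + 1L
    queue <- i
    comp_id[i] <- next_id
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      reach <- which(nbr[p, ] & is_core & comp_id == 0L)
      comp_id[reach] <- next_id
      queue <- c(queue, reach)
    }
  }

  # border points: nearest core point wins; ties to lower cluster id
  border <- which(!is_core)
  for (b in border) {
    cand <- which(nbr[b, ] & is_core)
    if (length(cand) == 0L) next
    d <- D[b, cand]
    best <- cand[d <= min(d) + 0]
    comp_id[b] <- min(comp_id[best])
  }

  ids <- setdiff(sort(unique(comp_id)), 0L)
  niches <- lapply(ids, function(k) {
    idx <- which(comp_id == k)
    new_niche(k, sub$cell_id[idx], xy[idx, , drop = FALSE],
              sub$cell_type[idx])
  })
  keep <- vapply(niches, function(nn) {
    nn$composition[["DC"]] >= params$min_dc &&
      (nn$composition[["T_CONV"]] + nn$composition[["T_REG"]]) >= params$min_t
  }, logical(1))
  niches <- niches[keep]
  if (length(niches) == 0L) return(empty)

  sizes <- vapply(niches, function(nn) length(nn$member_cell_ids), integer(1))
  cx <- vapply(niches, function(nn) nn$centroid[["x"]], numeric(1))
  cy <- vapply(niches, function(nn) nn$centroid[["y"]], numeric(1))
  o <- order(-sizes, cx, cy)
  niches <- niches[o]
  for (i in seq_along(niches)) niches[[i]]$niche_id <- i
  structure(niches, class = "niche_list")
}

#' @export
print.niche_list <- function(x, ...) {
  cat(sprintf("<niche_list> %d niche(s)\n", length(x)))
  invisible(x)
}

#' Niche list as a data frame
#'
#' @param x A `niche_list`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return One row per niche: id, member count, centroid, per-type
#'   composition, hull-area proxy, parenchymal flag.
#' @export
as.data.frame.niche_list <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  if (length(x) == 0L)
    return(data.frame(niche_id = integer(), n_members = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      n_dc = integer(), n_t_conv = integer(),
                      n_t_reg = integer(), area_um2 = numeric(),
                      is_parenchymal = logical()))
  data.frame(
    niche_id   = vapply(x, `[[`, integer(1), "niche_id"),
    n_members  = vapply(x, function(nn) length(nn$member_cell_ids), integer(1)),
    centroid_x = vapply(x, function(nn) nn$centroid[["x"]], numeric(1)),
    centroid_y = vapply(x, function(nn) nn$centroid[["y"]], numeric(1)),
    n_dc       = vapply(x, function(nn) nn$composition[["DC"]], integer(1)),
    n_t_conv   = vapply(x, function(nn) nn$composition[["T_CONV"]], integer(1)),
    n_t_reg    = vapply(x, function(nn) nn$composition[["T_REG"]], integer(1)),
    area_um2   = vapply(x, `[[`, numeric(1), "area_proxy"),
    is_parenchymal = vapply(x, function(nn) as.logical(nn$is_parenchymal),
                            logical(1)))
}

#' Distance from each T cell to its nearest dendritic cell
#'
#' For every T cell (conventional or regulatory) in the table, the Euclidean
#' distance in micrometers to the closest DC, plus the slide-level mean.
#' Adding DCs can only shrink the per-cell minima, so the mean is monotone
#' non-increasing in the DC set.
#'
#' @param cells A `cell_tbl` containing at least one DC and one T cell.
#' @return List with `distances` (named by T-cell id, input order) and
#'   `mean`.
#' @export
nearest_dc_distance <- function(cells) {
  t_idx <- which(cells$cell_type %in% c("T_CONV", "T_REG"))
  d_idx <- which(cells$cell_type == "DC")
  if (length(d_idx) == 0L)
    abort_domain("no DC present: distance undefined without reference population")
  if (length(t_idx) == 0L)
    abort_domain("no T cells present")
  dx <- outer(cells$x[t_idx], cells$x[d_idx], "-")
  dy <- outer(cells$y[t_idx], cells$y[d_idx], "-")
  M <- sqrt(dx * dx + dy * dy)
  dists <- apply(M, 1L, min)
  names(dists) <- cells$cell_id[t_idx]
  list(distances = dists, mean = mean(dists))
}

#' Niche (focus) density per square millimeter
#'
#' @param niches A `niche_list` (or anything with a length).
#' @param tissue_area Tissue area in mm^2 (> 0); see
#'   [tissue_area_estimate()].
#' @return Niches per mm^2.
#' @export
foci_density <- function(niches, tissue_area) {
  if (!is.finite(tissue_area) || tissue_area <= 0)
    abort_validation("tissue_area must be > 0")
  length(niches) / tissue_area
}

# distance from a point to one vessel feature (0 inside a polygon)
vessel_feature_distance <- function(px, py, f) {
  if (identical(f$type, "point"))
    return(sqrt((px - f$x)^2 + (py - f$y)^2))
  v <- f$vertices
  if (point_in_polygon(px, py, v)) return(0)
  n <- nrow(v)
  j <- c(2:n, 1L)
  min(vapply(seq_len(n), function(i)
    dist_point_segment(px, py, v[i, 1L], v[i, 2L], v[j[i], 1L], v[j[i], 2L]),
    numeric(1)))
}

point_in_polygon <- function(px, py, v) {
  # even-odd rule
  n <- nrow(v); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else max(0, min(1, ((px - x1) * vx + (py - y1) * vy) / L2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Classify niches as parenchymal or perivascular
#'
#' A niche is parenchymal when no vessel feature lies within
#' `proximity_radius` of its centroid: the distance to a vessel point is
#' Euclidean, to a polygon it is the distance to the boundary, and 0 if the
#' centroid falls inside the polygon. With an empty vessel geometry every
#' niche is parenchymal. The fraction is monotone non-increasing in the
#' radius.
#'
#' @param niches A `niche_list`.
#' @param vessels A `vessel_geometry` ([read_vessels()]).
#' @param proximity_radius Micrometers (> 0); default 50, about one
#'   portal-tract radius.
#' @return List with `niches` (flags filled in) and `parenchymal_fraction`
#'   (`NA` with attribute `undefined = TRUE` when there are no niches).
#' @export
classify_parenchymal <- function(niches, vessels, proximity_radius = 50) {
  if (!is.finite(proximity_radius) || proximity_radius <= 0)
    abort_validation("proximity_radius must be > 0")
  if (length(niches) == 0L)
    return(list(niches = niches,
                parenchymal_fraction = structure(NA_real_, undefined = TRUE)))
  flags <- vapply(niches, function(nn) {
    if (length(vessels$features) == 0L) return(TRUE)
    dmin <- min(vapply(vessels$features, function(f)
      vessel_feature_distance(nn$centroid[["x"]], nn$centroid[["y"]], f),
      numeric(1)))
    dmin > proximity_radius
  }, logical(1))
  for (i in seq_along(niches)) niches[[i]]$is_parenchymal <- flags[[i]]
  list(niches = niches, parenchymal_fraction = mean(flags))
}

#' Estimate tissue area from the cell map
#'
#' When no tissue mask accompanies the cell table, the slide area is
#' estimated from the cell positions themselves (all types): either the
#' convex-hull area, or an occupancy grid (`ALPHA_GRID`) counting
#' `grid_step`-sized squares containing at least one cell — a deliberately
#' coarse upper estimate at large steps, but robust to non-convex sections
#' and to collinear degenerate inputs.
#'
#' @param cells A `cell_tbl`.
#' @param method `"CONVEX_HULL"` (needs >= 3 non-collinear cells) or
#'   `"ALPHA_GRID"`.
#' @param grid_step Grid spacing in micrometers for `ALPHA_GRID` (> 0).
#' @return Area in mm^2.
#' @export
tissue_area_estimate <- function(cells,
                                 method = c("CONVEX_HULL", "ALPHA_GRID"),
                                 grid_step = 100) {
  method <- match.arg(method)
  xy <- cbind(cells$x, cells$y)
  if (method == "CONVEX_HULL") {
    a <- if (nrow(xy) >= 3L) hull_area(xy) else NA_real_
    if (is.na(a))
      abort_validation(
        "degenerate geometry for CONVEX_HULL (collinear or < 3 cells); use ALPHA_GRID")
    a / 1e6
  } else {
    if (!is.finite(grid_step) || grid_step <= 0)
      abort_validation("grid_step must be > 0")
    keys <- unique(paste(floor(xy[, 1L] / grid_step),
                         floor(xy[, 2L] / grid_step)))
    length(keys) * grid_step^2 / 1e6
  }
}

#' Per-cell niche membership labels
#'
#' Labels every cell of the table with the id of the niche whose member set
#' contains it, or `"NONE"`. Membership is by clustering, never by geometry:
#' an excluded-type cell lying inside a niche's hull stays `"NONE"`. Labeled
#' cell counts equal the summed niche member counts exactly.
#'
#' @param cells The `cell_tbl` the niches were detected from.
#' @param niches A `niche_list`.
#' @return Character vector along the rows of `cells`: `"niche_<id>"` or
#'   `"NONE"`.
#' @export
assign_niche_membership <- function(cells, niches) {
  labels <- rep("NONE", nrow(cells))
  names_idx <- stats::setNames(seq_len(nrow(cells)), cells$cell_id)
  for (nn in niches) {
    miss <- setdiff(nn$member_cell_ids, cells$cell_id)
    if (length(miss) > 0L)
      abort_validation(sprintf(
        "niche %d member(s) absent from cell table: %s", nn$niche_id,
        paste(miss, collapse = ", ")))
    labels[names_idx[nn$member_cell_ids]] <- paste0("niche_", nn$niche_id)
  }
  labels
}

#' Whole-slide spatial statistics
#'
#' Convenience wrapper computing the three slide-level quantities in one
#' call: mean nearest-DC distance over T cells, niche density per mm^2, and
#' (when vessel geometry is supplied) the parenchymal niche fraction.
#'
#' @param cells A `cell_tbl`.
#' @param niches A `niche_list` from [detect_microclusters()].
#' @param vessels Optional `vessel_geometry`; without it the parenchymal
#'   fraction is `NA`.
#' @param tissue_area Optional area in mm^2; estimated by convex hull when
#'   missing.
#' @param proximity_radius Passed to [classify_parenchymal()].
#' @return One-row data frame: `mean_nearest_dc_distance`, `n_niches`,
#'   `tissue_area_mm2`, `foci_density_per_mm2`, `parenchymal_fraction`.
#' @export
slide_stats <- function(cells, niches, vessels = NULL, tissue_area = NULL,
                        proximity_radius = 50) {
  area <- tissue_area %||% tissue_area_estimate(cells, "CONVEX_HULL")
  pf <- NA_real_
  if (!is.null(vessels) && length(niches) > 0L)
    pf <- classify_parenchymal(niches, vessels,
                               proximity_radius)$parenchymal_fraction
  data.frame(
    mean_nearest_dc_distance = nearest_dc_distance(cells)$mean,
    n_niches = length(niches),
    tissue_area_mm2 = area,
    foci_density_per_mm2 = foci_density(niches, area),
    parenchymal_fraction = pf)
}
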