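# Seeded generators for synthetic repertoires and tissues with known ground
# truth. Defaults describe the study conditions the pipeline targets: a
# ~4 mm^2 liver section with a sparse typed background point field and a
# handful of well-separated planted DC-T clumps, and per-mouse repertoires
# of a few hundred to a few thousand sequenced T cells.

#' Repertoire simulation parameters
#'
#' Clone sizes are drawn from `clone_size_law` until the target cell count
#' is reached (the last clone is truncated so the count is exact). Lineage
#' is drawn per clone — whole clones are Treg or Tconv with probability
#' `p_treg`, mirroring clonal lineage coherence — except that a fraction
#' `sharing_rate` of expanded clones is forced to contain both lineages,
#' making shared clones a controlled event rather than an incidental one.
#'
#' @param n_cells Total cells to generate (>= 1).
#' @param clone_size_law List: `list(law = "POWER_LAW", exponent = a)` with
#'   `a > 1` (sizes with probability proportional to `s^-a`),
#'   `list(law = "GEOMETRIC", p = p)` (size `1 + Geom(p)`, mean `1/p`), or
#'   `list(law = "UNIFORM", size = s)` (all clones size `s`).
#' @param p_treg Marginal Treg probability in \[0, 1\].
#' @param sharing_rate Probability that an expanded clone is forced to
#'   contain both lineages, in \[0, 1\].
#' @return Validated `repertoire_sim_params` list.
#' @export
repertoire_sim_params <- function(n_cells = 1000L,
                                  clone_size_law = list(law = "GEOMETRIC",
                                                        p = 0.7),
                                  p_treg = 0.3, sharing_rate = 0.1) {
  if (n_cells < 1L) abort_validation("n_cells must be >= 1")
  if (p_treg < 0 || p_treg > 1) abort_validation("p_treg must be in [0, 1]")
  if (sharing_rate < 0 || sharing_rate > 1)
    abort_validation("sharing_rate must be in [0, 1]")
  law <- clone_size_law$law %||% ""
  ok <- switch(law,
    POWER_LAW = is.numeric(clone_size_law$exponent) &&
      clone_size_law$exponent > 1,
    GEOMETRIC = is.numeric(clone_size_law$p) && clone_size_law$p > 0 &&
      clone_size_law$p <= 1,
    UNIFORM   = is.numeric(clone_size_law$size %||% 1) &&
      (clone_size_law$size %||% 1) >= 1,
    FALSE)
  if (!isTRUE(ok))
    abort_validation(sprintf("invalid clone_size_law (law '%s')", law))
  structure(list(n_cells = as.integer(n_cells),
                 clone_size_law = clone_size_law,
                 p_treg = p_treg, sharing_rate = sharing_rate),
            class = "repertoire_sim_params")
}

draw_clone_sizes <- function(law, n_cells) {
  draw <- switch(law$law,
    POWER_LAW = {
      support <- 1:10000
      prob <- support^(-law$exponent)
      function(k) sample(support, k, replace = TRUE, prob = prob)
    },
    GEOMETRIC = function(k) 1L + stats::rgeom(k, law$p),
    UNIFORM   = function(k) rep(as.integer(law$size %||% 1), k))
  sizes <- integer(0)
  total <- 0L
  while (total < n_cells) {
    chunk <- as.integer(draw(max(64L, ceiling(n_cells / 4))))
    sizes <- c(sizes, chunk)
    total <- sum(sizes)
  }
  cut <- which(cumsum(sizes) >= n_cells)[1L]
  sizes <- sizes[seq_len(cut)]
  truncated <- sum(sizes) - n_cells
  sizes[cut] <- sizes[cut] - truncated
  if (sizes[cut] == 0L) sizes <- sizes[-cut]
  structure(sizes, truncated = as.integer(truncated))
}

#' Simulate one subject's clonal repertoire
#'
#' @param params A [repertoire_sim_params()] object.
#' @param seed Integer seed; output is bit-reproducible given
#'   (params, seed).
#' @param subject_id,timepoint Labels stamped on every cell.
#' @return List with `repertoire` (a `repertoire_tbl`) and `truth` (the
#'   generating clone table: `clone_id`, `size`, `n_treg`, `n_tconv`,
#'   `category`, `forced_shared`), plus the number of cells truncated from
#'   the final clone in attribute `truncated` of `truth`.
#' @export
simulate_repertoire <- function(params, seed, subject_id = "sim1",
                                timepoint = "sim") {
  stopifnot(inherits(params, "repertoire_sim_params"))
  withr::with_seed(as.integer(seed), {
    sizes <- draw_clone_sizes(params$clone_size_law, params$n_cells)
    n_clones <- length(sizes)
    clone_ids <- sprintf("clone%05d", seq_len(n_clones))
    forced <- sizes > 1L & stats::runif(n_clones) < params$sharing_rate
    lineages <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      s <- sizes[i]
      if (forced[i]) {
        # pin one cell per lineage, remainder i.i.d.
        rest <- if (s > 2L)
          ifelse(stats::runif(s - 2L) < params$p_treg, "TREG", "TCONV")
        else character(0)
        lineages[[i]] <- c("TREG", "TCONV", rest)
      } else {
        lin <- if (stats::runif(1L) < params$p_treg) "TREG" else "TCONV"
        lineages[[i]] <- rep(lin, s)
      }
    }
    rep_df <- data.frame(
      cell_id    = sprintf("cell%06d", seq_len(sum(sizes))),
      subject_id = subject_id,
      timepoint  = timepoint,
      clone_id   = rep(clone_ids, sizes),
      lineage    = unlist(lineages),
      stringsAsFactors = FALSE)
    n_treg <- vapply(lineages, function(l) sum(l == "TREG"), integer(1))
    truth <- data.frame(clone_id = clone_ids, size = as.integer(sizes),
                        n_treg = n_treg, n_tconv = as.integer(sizes) - n_treg,
                        stringsAsFactors = FALSE)
    truth$category <- categorize_clone(truth$n_treg, truth$n_tconv)
    truth$forced_shared <- forced
    attr(truth, "truncated") <- attr(sizes, "truncated")
    list(repertoire = new_repertoire_tbl(rep_df), truth = truth)
  })
}

#' Tissue simulation parameters
#'
#' Emulates an in-situ transcriptomics cell map: homogeneous Poisson
#' background point fields per cell type over a rectangular section, planted
#' DC-T clumps (niches) with Poisson-drawn composition placed uniformly in
#' discs around well-separated centers, point vessels, and per-cell Poisson
#' gene counts with optional fold-change effects applied to niche members of
#' a matching type.
#'
#' Defaults describe a sparse neonatal-liver-like section: included-type
#' background of 100 cells/mm^2 (so an expected ~0.28 cells per 30-um disc),
#' niches of about 5 DCs and 12 T cells within a 20-um radius, and center
#' separation of at least 150 um.
#'
#' @param field_size Section width and height in micrometers.
#' @param background_intensity Named cells/mm^2 per type (`DC`, `T_CONV`,
#'   `T_REG`, `OTHER`).
#' @param n_niches Planted niche count.
#' @param niche_radius Disc radius (um) for member placement (> 0).
#' @param niche_composition Named means `c(dc = , t = )` for the
#'   Poisson-drawn member counts per niche.
#' @param p_treg_niche Probability a niche T cell is regulatory.
#' @param min_niche_separation Minimum center-to-center distance (um); must
#'   be at least `2 * niche_radius`.
#' @param n_vessels Random vessel points dropped uniformly on the field.
#' @param vessels_at_niches If `TRUE`, additionally place one vessel point
#'   at `vessel_offset` um from every niche center (the perivascular, adult
#'   -like arrangement).
#' @param vessel_offset Distance (um) for `vessels_at_niches`.
#' @param n_genes Panel size; 0 skips count generation.
#' @param gene_names Optional panel names (length `n_genes`).
#' @param baseline_expression Mean counts per gene per cell (scalar or
#'   per-gene vector; Poisson).
#' @param niche_effects `NULL` or a data frame with columns `cell_type`,
#'   `gene`, `fold_change` (> 0), applied inside niches.
#' @return Validated `tissue_sim_params` list.
#' @export
tissue_sim_params <- function(field_size = c(2000, 2000),
                              background_intensity = c(DC = 25, T_CONV = 50,
                                                       T_REG = 25,
                                                       OTHER = 300),
                              n_niches = 5L, niche_radius = 20,
                              niche_composition = c(dc = 5, t = 12),
                              p_treg_niche = 0.5,
                              min_niche_separation = 150,
                              n_vessels = 8L, vessels_at_niches = FALSE,
                              vessel_offset = 25,
                              n_genes = 0L, gene_names = NULL,
                              baseline_expression = 1,
                              niche_effects = NULL) {
  if (any(background_intensity < 0))
    abort_validation("background intensities must be >= 0")
  if (niche_radius <= 0) abort_validation("niche_radius must be > 0")
  if (min_niche_separation < 2 * niche_radius)
    abort_validation("min_niche_separation must be >= 2 * niche_radius")
  if (!is.null(niche_effects)) {
    stopifnot(all(c("cell_type", "gene", "fold_change") %in%
                    names(niche_effects)))
    if (any(niche_effects$fold_change <= 0))
      abort_validation("fold changes must be > 0")
  }
  if (is.null(gene_names) && n_genes > 0L)
    gene_names <- sprintf("gene%02d", seq_len(n_genes))
  if (n_genes > 0L && length(gene_names) != n_genes)
    abort_validation("gene_names length must equal n_genes")
  if (any(baseline_expression < 0))
    abort_validation("baseline_expression must be >= 0")
  structure(list(field_size = field_size,
                 background_intensity = background_intensity,
                 n_niches = as.integer(n_niches),
                 niche_radius = niche_radius,
                 niche_composition = niche_composition,
                 p_treg_niche = p_treg_niche,
                 min_niche_separation = min_niche_separation,
                 n_vessels = as.integer(n_vessels),
                 vessels_at_niches = isTRUE(vessels_at_niches),
                 vessel_offset = vessel_offset,
                 n_genes = as.integer(n_genes), gene_names = gene_names,
                 baseline_expression = baseline_expression,
                 niche_effects = niche_effects),
            class = "tissue_sim_params")
}

sample_niche_centers <- function(p) {
  w <- p$field_size[1L]; h <- p$field_size[2L]; r <- p$niche_radius
  centers <- matrix(numeric(0), ncol = 2L)
  attempts <- 0L
  while (nrow(centers) < p$n_niches) {
    attempts <- attempts + 1L
    if (attempts > 10000L)
      abort_generation(
        "could not place niche centers at the required separation; use fewer niches or a larger field")
    cand <- c(stats::runif(1, r, w - r), stats::runif(1, r, h - r))
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) >=
          p$min_niche_separation)
      centers <- rbind(centers, cand)
  }
  centers
}

#' Simulate a tissue section with planted microniches
#'
#' @param params A [tissue_sim_params()] object.
#' @param seed Integer seed; bit-reproducible given (params, seed).
#' @return List with `cells` (a `cell_tbl`), `counts` (genes x cells
#'   `dgCMatrix`, or `NULL` when `n_genes = 0`), `vessels`
#'   (`vessel_geometry`), and `truth` — a list with `centers` (matrix) and
#'   `niches` (per planted niche: center, member cell ids, type counts);
#'   member lists are disjoint by construction.
#' @export
simulate_tissue <- function(params, seed) {
  stopifnot(inherits(params, "tissue_sim_params"))
  p <- params
  withr::with_seed(as.integer(seed), {
    w <- p$field_size[1L]; h <- p$field_size[2L]
    area_mm2 <- w * h / 1e6

    bg <- lapply(names(p$background_intensity), function(tp) {
      n <- stats::rpois(1L, p$background_intensity[[tp]] * area_mm2)
      data.frame(x = stats::runif(n, 0, w), y = stats::runif(n, 0, h),
                 cell_type = rep(tp, n), stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, bg)
    cells$planted_niche <- rep(0L, nrow(cells))

    centers <- if (p$n_niches > 0L) sample_niche_centers(p) else
      matrix(numeric(0), ncol = 2L)
    for (k in seq_len(p$n_niches)) {
      n_dc <- stats::rpois(1L, p$niche_composition[["dc"]])
      n_t  <- stats::rpois(1L, p$niche_composition[["t"]])
      m <- n_dc + n_t
      if (m == 0L) next
      rad <- p$niche_radius * sqrt(stats::runif(m))
      th  <- stats::runif(m, 0, 2 * pi)
      t_types <- if (n_t > 0L)
        ifelse(stats::runif(n_t) < p$p_treg_niche, "T_REG", "T_CONV")
      else character(0)
      cells <- rbind(cells, data.frame(
        x = centers[k, 1L] + rad * cos(th),
        y = centers[k, 2L] + rad * sin(th),
        cell_type = c(rep("DC", n_dc), t_types),
        planted_niche = k, stringsAsFactors = FALSE))
    }
    cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))

    vessel_pts <- list()
    if (p$n_vessels > 0L) {
      vx <- stats::runif(p$n_vessels, 0, w)
      vy <- stats::runif(p$n_vessels, 0, h)
      vessel_pts <- Map(function(x, y) list(type = "point", x = x, y = y),
                        vx, vy)
    }
    if (p$vessels_at_niches && p$n_niches > 0L) {
      th <- stats::runif(p$n_niches, 0, 2 * pi)
      vessel_pts <- c(vessel_pts, Map(
        function(k, a) list(type = "point",
                            x = centers[k, 1L] + p$vessel_offset * cos(a),
                            y = centers[k, 2L] + p$vessel_offset * sin(a)),
        seq_len(p$n_niches), th))
    }
    vessels <- vessel_geometry(vessel_pts)

    counts <- NULL
    if (p$n_genes > 0L) {
      base <- rep(p$baseline_expression, length.out = p$n_genes)
      means <- matrix(base, nrow = p$n_genes, ncol = nrow(cells))
      if (!is.null(p$niche_effects)) {
        for (i in seq_len(nrow(p$niche_effects))) {
          gi <- match(p$niche_effects$gene[i], p$gene_names)
          if (is.na(gi))
            abort_validation(sprintf("niche_effects gene '%s' not in panel",
                                     p$niche_effects$gene[i]))
          hit <- cells$planted_niche > 0L &
            cells$cell_type == p$niche_effects$cell_type[i]
          means[gi, hit] <- means[gi, hit] * p$niche_effects$fold_change[i]
        }
      }
      counts <- Matrix::Matrix(
        stats::rpois(length(means), as.vector(means)),
        nrow = p$n_genes, ncol = nrow(cells), sparse = TRUE,
        dimnames = list(p$gene_names, cells$cell_id))
      counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
    }

    truth_niches <- lapply(seq_len(p$n_niches), function(k) {
      idx <- cells$planted_niche == k
      list(niche = k, center = unname(centers[k, ]),
           member_cell_ids = cells$cell_id[idx],
           n_dc = sum(idx & cells$cell_type == "DC"),
           n_t = sum(idx & cells$cell_type %in% c("T_CONV", "T_REG")))
    })
    cell_tbl <- new_cell_tbl(cells[, c("cell_id", "x", "y", "cell_type")])
    list(cells = cell_tbl, counts = counts, vessels = vessels,
         truth = list(centers = centers, niches = truth_niches))
  })
}

# panel used by the fixture suite: the probes carrying planted niche effects
# first, filler probes after
fixture_gene_panel <- function() {
  c("Ccr7", "Cd274", "Cd80", "Pdcd1lg2", "Ikzf2", "Cxcr3", "Cxcl10",
    sprintf("gene%02d", 8:30))
}

fixture_niche_effects <- function() {
  data.frame(
    cell_type   = c("DC", "DC", "DC", "DC", "T_CONV", "T_REG"),
    gene        = c("Ccr7", "Cd274", "Cd80", "Pdcd1lg2", "Ikzf2", "Ikzf2"),
    fold_change = c(4, 4, 4, 4, 4, 4),
    stringsAsFactors = FALSE)
}

#' Write the synthetic fixture suite
#'
#' Generates and writes a small fixed set of files emulating the study's
#' input kinds: three single-subject repertoires with increasing expansion
#' and sharing (a postnatal-day-4-like, a postnatal-day-7-like, and an
#' adult-like repertoire — the developmental trajectory in which expansion
#' and Treg/Tconv sharing peak in the second postnatal week), one
#' neonatal-like tissue whose niches sit in the parenchyma away from
#' vessels (with niche-conditional gene effects on the DC and T
#' compartments), and one adult-like tissue whose niches all have a vessel
#' in close proximity. A ground-truth JSON and a checksum manifest accompany
#' the files; everything is byte-stable given the seed.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, a data frame manifest (`file`, `md5`), also written to
#'   `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      abort_io(sprintf("cannot create directory %s", out_dir))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, 8L))
  files <- character(0)
  truth <- list(seed = as.integer(seed))

  rep_specs <- list(
    pnd4  = list(tp = "PND4",  law = list(law = "GEOMETRIC", p = 0.92),
                 sharing = 0.05),
    pnd7  = list(tp = "PND7",  law = list(law = "GEOMETRIC", p = 0.60),
                 sharing = 0.35),
    adult = list(tp = "adult", law = list(law = "GEOMETRIC", p = 0.96),
                 sharing = 0.02))
  for (i in seq_along(rep_specs)) {
    nm <- names(rep_specs)[i]; sp <- rep_specs[[i]]
    prm <- repertoire_sim_params(n_cells = 800L, clone_size_law = sp$law,
                                 p_treg = 0.35, sharing_rate = sp$sharing)
    sim <- simulate_repertoire(prm, seeds[i], subject_id = paste0(nm, "_1"),
                               timepoint = sp$tp)
    f <- file.path(out_dir, paste0("rep_", nm, ".tsv"))
    write_repertoire(sim$repertoire, f)
    files <- c(files, f)
    truth[[paste0("rep_", nm)]] <- list(
      n_cells = sum(sim$truth$size),
      n_clones = nrow(sim$truth),
      expanded_fraction = mean(sim$truth$size > 1),
      shared_clone_count = sum(sim$truth$category == "SHARED"))
  }

  neo_params <- tissue_sim_params(
    n_genes = 30L, gene_names = fixture_gene_panel(),
    baseline_expression = 1, niche_effects = fixture_niche_effects(),
    n_niches = 8L, niche_composition = c(dc = 8, t = 16),
    n_vessels = 6L, vessels_at_niches = FALSE)
  neo <- simulate_tissue(neo_params, seeds[4L])
  adult_params <- tissue_sim_params(n_niches = 5L, n_vessels = 4L,
                                    vessels_at_niches = TRUE)
  adl <- simulate_tissue(adult_params, seeds[5L])

  f_cells_neo <- file.path(out_dir, "cells_neonatal.csv")
  write_cell_table(neo$cells, f_cells_neo)
  f_mtx <- file.path(out_dir, "counts_neonatal.mtx")
  f_genes <- file.path(out_dir, "genes_neonatal.txt")
  f_cids <- file.path(out_dir, "cellids_neonatal.txt")
  write_counts_mtx(neo$counts, f_mtx, f_genes, f_cids)
  f_ves_neo <- file.path(out_dir, "vessels_neonatal.json")
  write_vessels(neo$vessels, f_ves_neo)
  f_cells_adl <- file.path(out_dir, "cells_adult.csv")
  write_cell_table(adl$cells, f_cells_adl)
  f_ves_adl <- file.path(out_dir, "vessels_adult.json")
  write_vessels(adl$vessels, f_ves_adl)
  files <- c(files, f_cells_neo, f_mtx, f_genes, f_cids, f_ves_neo,
             f_cells_adl, f_ves_adl)

  truth$tissue_neonatal <- list(
    n_niches = length(neo$truth$niches),
    niche_members = lapply(neo$truth$niches, `[[`, "member_cell_ids"))
  truth$tissue_adult <- list(
    n_niches = length(adl$truth$niches),
    niche_members = lapply(adl$truth$niches, `[[`, "member_cell_ids"))

  f_truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_truth)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
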