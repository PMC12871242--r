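as_cells <- function(x, y, type, ids = sprintf("c%03d", seq_along(x))) {
  structure(data.frame(cell_id = ids, x = x, y = y, cell_type = type,
                       stringsAsFactors = FALSE),
            class = c("cell_tbl", "data.frame"))
}

test_that("a single dense DC-T clump yields exactly one niche", {
  set.seed(21)
  th <- runif(8, 0, 2 * pi); r <- 20 * sqrt(runif(8))
  cells <- as_cells(100 + r * cos(th), 100 + r * sin(th),
                    c("DC", "DC", rep("T_CONV", 3), rep("T_REG", 3)))
  niches <- detect_microclusters(cells, niche_params(eps = 30,
                                                     min_samples = 4))
  expect_length(niches, 1L)
  expect_setequal(niches[[1]]$member_cell_ids, cells$cell_id)
  expect_equal(unname(niches[[1]]$composition[c("DC", "T_CONV", "T_REG")]),
               c(2L, 3L, 3L))
})

test_that("sparse fields give no niches and empty input is not an error", {
  cells <- as_cells(seq(0, 900, by = 100), rep(0, 10),
                    rep(c("DC", "T_CONV"), 5))
  expect_length(detect_microclusters(cells, niche_params(eps = 30)), 0L)
  empty <- as_cells(numeric(0), numeric(0), character(0), character(0))
  expect_length(detect_microclusters(empty), 0L)
  expect_error(niche_params(eps = -1), class = "cloniche_validation_error")
})

test_that("well-separated planted clumps are each recovered exactly", {
  set.seed(22)
  eps <- 30
  centers <- cbind(c(100, 500, 900, 100, 900), c(100, 500, 900, 900, 100))
  xs <- c(); ys <- c(); tps <- c()
  for (k in 1:5) {
    m <- 6  # 1 DC + 5 T
    th <- runif(m, 0, 2 * pi); r <- (eps / 3) * sqrt(runif(m))
    xs <- c(xs, centers[k, 1] + r * cos(th))
    ys <- c(ys, centers[k, 2] + r * sin(th))
    tps <- c(tps, c("DC", rep("T_CONV", 5)))
  }
  cells <- as_cells(xs, ys, tps)
  params <- niche_params(eps = eps, min_samples = 4)
  niches <- detect_microclusters(cells, params)
  expect_length(niches, 5L)
  got <- sort_sets(niche_member_sets(niches))
  want <- sort_sets(lapply(0:4, function(k)
    sort(cells$cell_id[k * 6 + 1:6])))
  expect_equal(got, want)
  # and equals the naive quadratic reference
  ref <- sort_sets(reference_niche_sets(cells, eps, 4, 1, 3))
  expect_equal(got, ref)
})

test_that("clustering is invariant to row permutation and rigid motion", {
  set.seed(23)
  for (i in 1:5) {
    cells <- random_cell_table(150, field = 300)
    params <- niche_params(eps = 30, min_samples = 4, min_dc = 1, min_t = 1)
    base <- sort_sets(niche_member_sets(detect_microclusters(cells, params)))
    perm <- structure(as.data.frame(cells)[sample(nrow(cells)), ],
                      class = c("cell_tbl", "data.frame"))
    expect_equal(sort_sets(niche_member_sets(
      detect_microclusters(perm, params))), base)
    a <- runif(1, 0, 2 * pi)
    rot <- cells
    rot$x <- cos(a) * cells$x - sin(a) * cells$y + 500
    rot$y <- sin(a) * cells$x + cos(a) * cells$y - 200
    expect_equal(sort_sets(niche_member_sets(
      detect_microclusters(rot, params))), base)
  }
})

test_that("niche ordering and ids are deterministic", {
  set.seed(24)
  clump <- function(cx, cy, n_dc, n_t) {
    m <- n_dc + n_t
    th <- runif(m, 0, 2 * pi); r <- 10 * sqrt(runif(m))
    data.frame(x = cx + r * cos(th), y = cy + r * sin(th),
               cell_type = c(rep("DC", n_dc), rep("T_CONV", n_t)),
               stringsAsFactors = FALSE)
  }
  df <- rbind(clump(100, 100, 1, 4), clump(700, 700, 2, 10),
              clump(400, 100, 1, 6))
  df$cell_id <- sprintf("c%03d", seq_len(nrow(df)))
  cells <- structure(df, class = c("cell_tbl", "data.frame"))
  niches <- detect_microclusters(cells, niche_params(eps = 30,
                                                     min_samples = 3))
  expect_length(niches, 3L)
  sizes <- vapply(niches, function(nn) length(nn$member_cell_ids),
                  integer(1))
  expect_equal(sizes, c(12L, 7L, 5L))                 # descending member count
  expect_equal(vapply(niches, `[[`, integer(1), "niche_id"), 1:3)
})

test_that("nearest-DC distances: coincident, 3-4-5, and all-pairs oracle", {
  cells <- as_cells(c(0, 0), c(0, 0), c("T_CONV", "DC"))
  expect_equal(unname(nearest_dc_distance(cells)$distances), 0)

  tri <- as_cells(c(0, 3, 6), c(0, 4, 8), c("T_REG", "DC", "DC"))
  expect_equal(unname(nearest_dc_distance(tri)$distances), 5.0)

  expect_error(nearest_dc_distance(as_cells(0, 0, "T_CONV")),
               class = "cloniche_domain_error")

  set.seed(25)
  cells <- as_cells(runif(340, 0, 1000), runif(340, 0, 1000),
                    c(rep("T_CONV", 200), rep("T_REG", 100), rep("DC", 40)))
  res <- nearest_dc_distance(cells)
  expect_equal(unname(res$distances), brute_nearest_dc(cells))
  expect_equal(res$mean, mean(brute_nearest_dc(cells)))
})

test_that("adding DCs never increases the mean nearest-DC distance", {
  set.seed(26)
  cells <- as_cells(runif(120, 0, 500), runif(120, 0, 500),
                    c(rep("T_CONV", 100), rep("DC", 20)))
  m1 <- nearest_dc_distance(cells)$mean
  extra <- as_cells(runif(10, 0, 500), runif(10, 0, 500), rep("DC", 10),
                    ids = sprintf("x%02d", 1:10))
  more <- structure(rbind(as.data.frame(cells), as.data.frame(extra)),
                    class = c("cell_tbl", "data.frame"))
  expect_lte(nearest_dc_distance(more)$mean, m1)
})

test_that("foci density is count over area and rejects bad areas", {
  expect_equal(foci_density(list(), 3.5), 0)
  expect_equal(foci_density(vector("list", 10), 2), 5)
  expect_error(foci_density(list(), 0), class = "cloniche_validation_error")
})

test_that("parenchyma classification follows the proximity rule exactly", {
  mk_niche <- function(x, y) list(niche_id = 1L, member_cell_ids = "c",
                                  centroid = c(x = x, y = y),
                                  composition = c(DC = 1L, T_CONV = 3L,
                                                  T_REG = 0L, OTHER = 0L),
                                  area_proxy = NA, is_parenchymal = NA)
  niches <- structure(list(mk_niche(0, 0), mk_niche(100, 0),
                           mk_niche(0, 100), mk_niche(100, 100)),
                      class = "niche_list")
  # no vessels -> all parenchymal
  res <- classify_parenchymal(niches, vessel_geometry(), 50)
  expect_equal(res$parenchymal_fraction, 1.0)
  # vessel point at every centroid -> none
  at_all <- vessel_geometry(lapply(niches, function(nn)
    list(type = "point", x = nn$centroid[["x"]], y = nn$centroid[["y"]])))
  expect_equal(classify_parenchymal(niches, at_all, 50)$parenchymal_fraction,
               0.0)
  # 2 niches with a vessel at radius/2, 2 with nearest vessel at 3*radius
  v <- vessel_geometry(list(list(type = "point", x = 25, y = 0),
                            list(type = "point", x = 100, y = 25),
                            list(type = "point", x = -150, y = 100),
                            list(type = "point", x = 250, y = 100)))
  expect_equal(classify_parenchymal(niches, v, 50)$parenchymal_fraction, 0.5)
})

test_that("centroids inside a vessel polygon are non-parenchymal", {
  mk_niche <- function(x, y) list(niche_id = 1L, member_cell_ids = "c",
                                  centroid = c(x = x, y = y),
                                  composition = c(DC = 1L, T_CONV = 3L,
                                                  T_REG = 0L, OTHER = 0L),
                                  area_proxy = NA, is_parenchymal = NA)
  poly <- rbind(c(0, 0), c(200, 0), c(200, 200), c(0, 200))
  v <- vessel_geometry(list(list(type = "polygon", vertices = poly)))
  inside <- structure(list(mk_niche(100, 100)), class = "niche_list")
  far <- structure(list(mk_niche(500, 500)), class = "niche_list")
  expect_equal(classify_parenchymal(inside, v, 50)$parenchymal_fraction, 0)
  expect_equal(classify_parenchymal(far, v, 50)$parenchymal_fraction, 1)
  # ray-casting oracle agrees with the package's point-in-polygon
  set.seed(27)
  for (i in 1:50) {
    px <- runif(1, -50, 250); py <- runif(1, -50, 250)
    expect_equal(cloniche:::point_in_polygon(px, py, poly),
                 ray_cast_inside(px, py, poly[, 1], poly[, 2]))
  }
})

test_that("parenchymal fraction is monotone non-increasing in radius", {
  set.seed(28)
  mk_niche <- function(x, y) list(niche_id = 1L, member_cell_ids = "c",
                                  centroid = c(x = x, y = y),
                                  composition = c(DC = 1L, T_CONV = 3L,
                                                  T_REG = 0L, OTHER = 0L),
                                  area_proxy = NA, is_parenchymal = NA)
  for (i in 1:10) {
    niches <- structure(lapply(1:6, function(k)
      mk_niche(runif(1, 0, 500), runif(1, 0, 500))), class = "niche_list")
    v <- vessel_geometry(lapply(1:4, function(k)
      list(type = "point", x = runif(1, 0, 500), y = runif(1, 0, 500))))
    fr <- vapply(c(10, 50, 100, 200, 400), function(r)
      classify_parenchymal(niches, v, r)$parenchymal_fraction, numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("tissue area estimates: square hull, coarse grid, shoelace oracle", {
  sq <- as_cells(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), rep("OTHER", 4))
  expect_equal(tissue_area_estimate(sq, "CONVEX_HULL"), 1.0)
  expect_equal(tissue_area_estimate(sq, "ALPHA_GRID", grid_step = 1000), 4.0)

  line <- as_cells(c(0, 1, 2), c(0, 1, 2), rep("OTHER", 3))
  expect_error(tissue_area_estimate(line, "CONVEX_HULL"),
               class = "cloniche_validation_error")

  set.seed(29)
  pts <- as_cells(runif(50, 0, 800), runif(50, 0, 800), rep("OTHER", 50))
  h <- grDevices::chull(cbind(pts$x, pts$y))
  expect_equal(tissue_area_estimate(pts, "CONVEX_HULL"),
               shoelace(pts$x[h], pts$y[h]) / 1e6)
})

test_that("membership labels partition exactly and are by clustering only", {
  set.seed(30)
  sim <- simulate_tissue(tissue_sim_params(n_niches = 3), seed = 5)
  niches <- detect_microclusters(sim$cells)
  mem <- assign_niche_membership(sim$cells, niches)
  expect_length(mem, nrow(sim$cells))
  expect_equal(sum(mem != "NONE"),
               sum(vapply(niches, function(nn) length(nn$member_cell_ids),
                          integer(1))))
  # OTHER cells can sit inside a niche hull yet are never members
  expect_true(all(mem[sim$cells$cell_type == "OTHER"] == "NONE"))
  # member absent from the table is a consistency error
  if (length(niches) > 0) {
    broken <- niches
    broken[[1]]$member_cell_ids <- c(broken[[1]]$member_cell_ids, "ghost")
    expect_error(assign_niche_membership(sim$cells, broken),
                 class = "cloniche_validation_error")
  }
})
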