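#' @importFrom utils read.table write.table
#' @importFrom methods as is
NULL

# ---- shared helpers ---------------------------------------------------------

#' Cell lineage and cell-type vocabularies
#'
#' The two-value Foxp3 lineage enum used throughout the repertoire module and
#' the four-value cell-type enum used by the spatial module. Unknown cell-type
#' strings are mapped to `"OTHER"` on read.
#'
#' @name vocabularies
#' @keywords internal
LINEAGES   <- c("TREG", "TCONV")
CELL_TYPES <- c("DC", "T_CONV", "T_REG", "OTHER")
CLONE_CATEGORIES <- c("TREG_ONLY", "TCONV_ONLY", "SHARED")

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

read_delim_file <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  read.table(path, sep = detect_sep(path, sep), header = TRUE,
             colClasses = "character", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

check_column_map <- function(df, column_map, required, what) {
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles) > 0L)
    abort_config(sprintf("%s column_map is missing required role(s): %s",
                         what, paste(missing_roles, collapse = ", ")))
  cols <- unlist(column_map[required], use.names = TRUE)
  absent <- cols[!cols %in% names(df)]
  if (length(absent) > 0L)
    abort_config(sprintf(
      "%s file lacks column '%s' (mapped from role '%s')",
      what, absent[[1L]], names(absent)[[1L]]))
  invisible(TRUE)
}

# full-precision numeric formatting: round-trips doubles through text
fmt_num <- function(x) sprintf("%.15g", x)

# ---- repertoire tables ------------------------------------------------------

#' Default lineage value sets
#'
#' Source files encode Foxp3 status heterogeneously; these (case-insensitive)
#' value sets map raw strings onto the `TREG`/`TCONV` enum and can be extended
#' or replaced via the `lineage_values` argument of [read_repertoire()].
#'
#' @return A named list with components `TREG` and `TCONV`, each a character
#'   vector of accepted (lower-cased) raw values.
#' @export
default_lineage_values <- function() {
  list(TREG  = c("treg", "t_reg", "foxp3+", "foxp3_pos", "foxp3pos"),
       TCONV = c("tconv", "t_conv", "foxp3-", "foxp3_neg", "foxp3neg", "conv"))
}

new_repertoire_tbl <- function(df, n_dropped = 0L) {
  rownames(df) <- NULL
  structure(df, class = c("repertoire_tbl", "data.frame"),
            n_dropped = as.integer(n_dropped))
}

validate_repertoire_tbl <- function(df) {
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup) > 0L)
    abort_validation(sprintf("duplicate cell_id(s): %s",
                             paste(unique(dup), collapse = ", ")))
  if (any(!df$lineage %in% LINEAGES))
    abort_validation("lineage values must be TREG or TCONV")
  invisible(df)
}

#' Read a per-cell clonotype table
#'
#' Reads an AIRR-style / 10x-VDJ-style delimited text file into a validated
#' repertoire table with one row per sequenced T cell. Columns are mapped onto
#' the required roles via `column_map`, so exports with arbitrary column names
#' (e.g. `raw_clonotype_id`, `barcode`) can be ingested without preprocessing.
#' Rows with an empty `clone_id` (cells without a called clonotype) are
#' dropped; the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param path Path to a tab- or comma-separated file (delimiter auto-detected
#'   from the extension, `.csv` meaning comma; override with `sep`).
#' @param column_map Named list mapping the roles `cell_id`, `subject_id`,
#'   `clone_id`, `lineage` (and optionally `timepoint`) to column names in the
#'   file.
#' @param sep Optional delimiter override.
#' @param lineage_values Named list of accepted raw values per lineage, as
#'   returned by [default_lineage_values()]. Matching is case-insensitive.
#' @return A `repertoire_tbl` (data frame with columns `cell_id`,
#'   `subject_id`, `timepoint`, `clone_id`, `lineage`), with attribute
#'   `n_dropped` giving the count of rows dropped for empty `clone_id`.
#'   Row order is input order.
#' @export
read_repertoire <- function(path,
                            column_map = list(cell_id = "cell_id",
                                              subject_id = "subject_id",
                                              clone_id = "clone_id",
                                              lineage = "lineage",
                                              timepoint = "timepoint"),
                            sep = NULL,
                            lineage_values = default_lineage_values()) {
  df <- read_delim_file(path, sep)
  check_column_map(df, column_map,
                   c("cell_id", "subject_id", "clone_id", "lineage"),
                   "repertoire")
  out <- data.frame(
    cell_id    = df[[column_map$cell_id]],
    subject_id = df[[column_map$subject_id]],
    clone_id   = df[[column_map$clone_id]],
    lineage    = df[[column_map$lineage]],
    stringsAsFactors = FALSE)
  tp_col <- column_map$timepoint
  out$timepoint <- if (!is.null(tp_col) && tp_col %in% names(df))
    df[[tp_col]] else NA_character_

  empty <- is.na(out$clone_id) | trimws(out$clone_id) == ""
  n_dropped <- sum(empty)
  out <- out[!empty, , drop = FALSE]

  raw <- tolower(trimws(out$lineage))
  lin <- rep(NA_character_, length(raw))
  lin[raw %in% tolower(lineage_values$TREG)]  <- "TREG"
  lin[raw %in% tolower(lineage_values$TCONV)] <- "TCONV"
  if (anyNA(lin)) {
    bad <- which(is.na(lin))[1L]
    abort_validation(sprintf(
      "unparseable lineage value '%s' at row %d", out$lineage[bad], bad))
  }
  out$lineage <- lin
  out <- out[, c("cell_id", "subject_id", "timepoint", "clone_id", "lineage")]
  validate_repertoire_tbl(out)
  new_repertoire_tbl(out, n_dropped)
}

#' Write a repertoire table
#'
#' Inverse of [read_repertoire()] with identity column mapping: a written file
#' read back yields an identical table.
#'
#' @param x A `repertoire_tbl`.
#' @param path Output path; delimiter from extension (override with `sep`).
#' @param sep Optional delimiter override.
#' @return Invisibly, `path`.
#' @export
write_repertoire <- function(x, path, sep = NULL) {
  write.table(as.data.frame(x), path, sep = detect_sep(path, sep),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- cell tables ------------------------------------------------------------

#' Default cell-type value sets
#'
#' Maps raw cell-type strings (case-insensitive) onto the spatial module's
#' `DC` / `T_CONV` / `T_REG` / `OTHER` enum. Any string not covered maps to
#' `OTHER` with a warning count.
#'
#' @return Named list of accepted (lower-cased) raw values per type.
#' @export
default_type_values <- function() {
  list(DC     = c("dc", "cdc1", "cdc2", "dendritic"),
       T_CONV = c("t_conv", "tconv", "t cell", "tcell"),
       T_REG  = c("t_reg", "treg"),
       OTHER  = c("other"))
}

new_cell_tbl <- function(df, n_unknown_type = 0L) {
  rownames(df) <- NULL
  structure(df, class = c("cell_tbl", "data.frame"),
            n_unknown_type = as.integer(n_unknown_type))
}

#' Read a spatial cell table
#'
#' Reads a delimited cell table from imaging or in-situ transcriptomics (one
#' row per segmented cell: id, centroid in micrometers, cell-type label).
#' Coordinates are in micrometers with arbitrary origin; all downstream
#' statistics are invariant to translation and rotation, so axis orientation
#' does not matter. Cell-type strings outside the known vocabulary map to
#' `OTHER`; the count of such rows is kept in the `n_unknown_type` attribute.
#'
#' @param path Delimited text file.
#' @param column_map Named list mapping roles `cell_id`, `x`, `y`, `cell_type`
#'   to column names.
#' @param sep Optional delimiter override.
#' @param type_values Accepted raw values per cell type, as
#'   [default_type_values()].
#' @return A `cell_tbl` data frame (`cell_id`, `x`, `y`, `cell_type`), row
#'   order preserved, with attribute `n_unknown_type`.
#' @export
read_cell_table <- function(path,
                            column_map = list(cell_id = "cell_id", x = "x",
                                              y = "y", cell_type = "cell_type"),
                            sep = NULL,
                            type_values = default_type_values()) {
  df <- read_delim_file(path, sep)
  check_column_map(df, column_map, c("cell_id", "x", "y", "cell_type"),
                   "cell table")
  xs <- suppressWarnings(as.numeric(df[[column_map$x]]))
  ys <- suppressWarnings(as.numeric(df[[column_map$y]]))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad) > 0L)
    abort_validation(sprintf("non-numeric or non-finite coordinate at row %d",
                             bad[1L]))
  raw <- tolower(trimws(df[[column_map$cell_type]]))
  ct <- rep(NA_character_, length(raw))
  for (tp in names(type_values)) ct[raw %in% tolower(type_values[[tp]])] <- tp
  n_unknown <- sum(is.na(ct))
  ct[is.na(ct)] <- "OTHER"
  out <- data.frame(cell_id = df[[column_map$cell_id]], x = xs, y = ys,
                    cell_type = ct, stringsAsFactors = FALSE)
  dup <- out$cell_id[duplicated(out$cell_id)]
  if (length(dup) > 0L)
    abort_validation(sprintf("duplicate cell_id(s): %s",
                             paste(unique(dup), collapse = ", ")))
  new_cell_tbl(out, n_unknown)
}

#' Write a spatial cell table
#'
#' Inverse of [read_cell_table()]; coordinates are written at full double
#' precision so a written file reads back field-for-field identical.
#'
#' @inheritParams write_repertoire
#' @export
write_cell_table <- function(x, path, sep = NULL) {
  df <- as.data.frame(x)
  df$x <- fmt_num(df$x)
  df$y <- fmt_num(df$y)
  write.table(df, path, sep = detect_sep(path, sep), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- count matrices ---------------------------------------------------------

validate_count_matrix <- function(m) {
  if (any(m@x < 0)) abort_validation("count matrix has negative entries")
  if (any(m@x != floor(m@x)))
    abort_validation("count matrix has fractional entries")
  gn <- rownames(m)
  if (is.null(gn) || anyDuplicated(gn))
    abort_validation("gene names must be present and unique")
  invisible(m)
}

#' Read a sparse gene-count matrix (MatrixMarket triplet + name lists)
#'
#' Reads the conventional genes-by-cells trio: a MatrixMarket coordinate file
#' plus one-name-per-line gene and cell lists whose lengths must match the
#' matrix dimensions. Entries must be non-negative integers.
#'
#' @param matrix_path `.mtx` coordinate file.
#' @param genes_path Plain-text gene names, one per line (rows).
#' @param cells_path Plain-text cell ids, one per line (columns).
#' @return A `dgCMatrix` (genes x cells) with dimnames attached.
#' @export
read_counts_mtx <- function(matrix_path, genes_path, cells_path) {
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p)) abort_io(sprintf("file not found: %s", p))
  m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (length(genes) != nrow(m))
    abort_validation(sprintf(
      "gene list length (%d) does not match matrix rows (%d)",
      length(genes), nrow(m)))
  if (length(cells) != ncol(m))
    abort_validation(sprintf(
      "cell list length (%d) does not match matrix columns (%d)",
      length(cells), ncol(m)))
  dimnames(m) <- list(genes, cells)
  validate_count_matrix(m)
  m
}

#' Write a sparse gene-count matrix
#'
#' Inverse of [read_counts_mtx()]: writes the MatrixMarket coordinate file and
#' the two name lists. All stored entries are preserved exactly.
#'
#' @param m Genes x cells sparse matrix with dimnames.
#' @inheritParams read_counts_mtx
#' @export
write_counts_mtx <- function(m, matrix_path, genes_path, cells_path) {
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), cells_path)
  invisible(matrix_path)
}

# ---- vessel geometry --------------------------------------------------------

polygon_area <- function(xy) {
  # shoelace; xy is an n x 2 matrix of vertices (closed implicitly)
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

new_vessel_geometry <- function(features) {
  structure(list(features = features), class = "vessel_geometry")
}

validate_vessel_feature <- function(f, i) {
  if (identical(f$type, "point")) {
    if (!is.finite(f$x) || !is.finite(f$y))
      abort_validation(sprintf("vessel feature %d: non-finite point", i))
  } else if (identical(f$type, "polygon")) {
    v <- f$vertices
    if (!is.matrix(v) || nrow(v) < 3L)
      abort_validation(sprintf("vessel feature %d: polygon needs >= 3 vertices", i))
    if (!all(is.finite(v)))
      abort_validation(sprintf("vessel feature %d: non-finite vertices", i))
    if (polygon_area(v) <= 0)
      abort_validation(sprintf("vessel feature %d: degenerate (zero-area) polygon", i))
  } else {
    abort_validation(sprintf("vessel feature %d: unknown type '%s'", i, f$type))
  }
  invisible(f)
}

#' Vessel geometry constructor
#'
#' Builds a validated vessel-geometry object from a list of features, each
#' either `list(type = "point", x =, y =)` or
#' `list(type = "polygon", vertices = <n x 2 matrix>)`, coordinates in
#' micrometers. Polygons must have at least 3 vertices and non-zero area.
#'
#' @param features List of point/polygon features (possibly empty).
#' @return A `vessel_geometry` object.
#' @export
vessel_geometry <- function(features = list()) {
  for (i in seq_along(features))
    validate_vessel_feature(features[[i]], i)
  new_vessel_geometry(features)
}

#' Read vessel geometry
#'
#' Accepts either a GeoJSON-style JSON feature list (objects with `type`
#' `"point"` or `"polygon"`) or a two-column point CSV (`x`, `y` header).
#' An empty feature list is valid: with no vessels every niche is classified
#' parenchymal downstream.
#'
#' @param path `.json` feature file or `.csv`/`.tsv` point table.
#' @return A `vessel_geometry` object.
#' @export
read_vessels <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- lapply(raw, function(f) {
      if (identical(f$type, "point"))
        list(type = "point", x = as.numeric(f$x), y = as.numeric(f$y))
      else if (identical(f$type, "polygon"))
        list(type = "polygon",
             vertices = do.call(rbind, lapply(f$vertices, as.numeric)))
      else f
    })
    vessel_geometry(feats)
  } else {
    df <- read_delim_file(path)
    if (!all(c("x", "y") %in% names(df)))
      abort_config("vessel point file must have 'x' and 'y' columns")
    xs <- as.numeric(df$x); ys <- as.numeric(df$y)
    vessel_geometry(Map(function(x, y) list(type = "point", x = x, y = y),
                        xs, ys))
  }
}

#' Write vessel geometry as JSON
#'
#' Inverse of [read_vessels()] for the JSON representation; keys are written
#' in a fixed order so output is byte-stable for identical input.
#'
#' @param v A `vessel_geometry`.
#' @param path Output `.json` path.
#' @export
write_vessels <- function(v, path) {
  feats <- lapply(v$features, function(f) {
    if (identical(f$type, "point"))
      list(type = "point", x = f$x, y = f$y)
    else
      list(type = "polygon",
           vertices = lapply(seq_len(nrow(f$vertices)),
                             function(i) as.numeric(f$vertices[i, ])))
  })
  jsonlite::write_json(feats, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
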