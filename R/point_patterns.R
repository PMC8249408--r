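# Marked 2-D cell point patterns: data model, validation, tabular I/O.
#
# A pattern is one patient's cells as (x, y) coordinates in micrometers with a
# phenotype mark (B, T lineage, cancer, other) and a tissue-category mark
# (cancer_island vs stroma), plus a region of interest (ROI) whose area in mm^2
# is the denominator for every density downstream.

#' Recognized phenotype levels
#'
#' `T` denotes CD3+ T cells when subtypes are unavailable; `T_CD8`, `T_helper`
#' and `Treg` all count as CD3+ T lineage. A cell is a lymphocyte iff its
#' phenotype is B or any T-lineage level.
#' @export
PHENOTYPE_LEVELS <- c("B", "T", "T_CD8", "T_helper", "Treg", "cancer", "other")

#' Phenotypes counted as lymphocytes
#' @export
LYMPHOCYTE_PHENOTYPES <- c("B", "T", "T_CD8", "T_helper", "Treg")

#' Phenotypes counted as CD3+ T lineage
#' @export
T_LINEAGE_PHENOTYPES <- c("T", "T_CD8", "T_helper", "Treg")

#' Recognized tissue categories
#' @export
TISSUE_LEVELS <- c("cancer_island", "stroma")

OUTCOME_LEVELS <- c("good", "poor", "normal", "unlabeled")

#' Is a phenotype a lymphocyte?
#'
#' @param phenotype character vector of phenotype levels.
#' @return logical vector.
#' @export
is_lymphocyte <- function(phenotype) phenotype %in% LYMPHOCYTE_PHENOTYPES

#' Default label-normalization table for phenotype marks
#'
#' Maps raw marker labels (as emitted by upstream phenotyping software, case
#' insensitive) onto the package's phenotype levels. Staining panels differ
#' between studies, so the table is configuration, not convention.
#'
#' @return named character vector: names are lowercased raw labels, values are
#'   members of [PHENOTYPE_LEVELS].
#' @export
default_phenotype_map <- function() {
  c(
    "b" = "B", "cd20" = "B", "cd20+" = "B", "b cell" = "B", "b_cell" = "B",
    "t" = "T", "cd3" = "T", "cd3+" = "T", "t cell" = "T", "t_cell" = "T",
    "t_cd8" = "T_CD8", "cd8" = "T_CD8", "cd8+" = "T_CD8", "cytotoxic" = "T_CD8",
    "t_helper" = "T_helper", "th" = "T_helper", "cd4" = "T_helper",
    "helper" = "T_helper",
    "treg" = "Treg", "foxp3" = "Treg", "foxp3+" = "Treg",
    "cancer" = "cancer", "ck" = "cancer", "panck" = "cancer",
    "pan-ck" = "cancer", "tumor" = "cancer", "epithelial" = "cancer",
    "other" = "other", "stromal" = "other", "dapi" = "other"
  )
}

default_tissue_map <- function() {
  c(
    "cancer_island" = "cancer_island", "cancerisland" = "cancer_island",
    "cancer island" = "cancer_island", "cancer" = "cancer_island",
    "tumor" = "cancer_island", "island" = "cancer_island", "ci" = "cancer_island",
    "stroma" = "stroma", "stromal" = "stroma", "non-tumor" = "stroma"
  )
}

normalize_labels <- function(x, map, what) {
  x <- as.character(x)
  key <- tolower(trimws(x))
  hit <- map[key]
  bad <- which(is.na(hit))
  if (length(bad) > 0) {
    stop(sprintf(
      "unmappable %s label(s) %s at row(s) %s", what,
      paste(unique(sQuote(x[bad])), collapse = ", "),
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  warn_rows <- which(x != unname(hit))
  if (length(warn_rows) > 0) {
    warning(sprintf("%d %s label(s) normalized via alias table", length(warn_rows), what),
            call. = FALSE)
  }
  unname(hit)
}

#' Construct a region of interest
#'
#' @param area_mm2 ROI area in mm^2 (must be positive). If `NULL` and a
#'   boundary is given, the area is computed from the polygon.
#' @param boundary optional polygon as a two-column matrix of (x, y) vertices
#'   in micrometers (closed implicitly; do not repeat the first vertex).
#' @return an object of class `til_roi`.
#' @export
roi <- function(area_mm2 = NULL, boundary = NULL) {
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    if (ncol(boundary) != 2 || nrow(boundary) < 3)
      stop("boundary must be a matrix of >= 3 (x, y) vertices", call. = FALSE)
    storage.mode(boundary) <- "double"
    poly_mm2 <- polygon_area(boundary) / 1e6
    if (is.null(area_mm2)) area_mm2 <- poly_mm2
    else if (abs(poly_mm2 - area_mm2) > 1e-3 * abs(area_mm2))
      stop(sprintf("boundary polygon area (%.6g mm^2) disagrees with area_mm2 (%.6g mm^2)",
                   poly_mm2, area_mm2), call. = FALSE)
  }
  if (is.null(area_mm2) || !is.finite(area_mm2) || area_mm2 <= 0)
    stop("ROI area must be a positive finite number (mm^2)", call. = FALSE)
  structure(list(boundary = boundary, area_mm2 = as.numeric(area_mm2)),
            class = "til_roi")
}

#' Shoelace area of a simple polygon (input units squared)
#' @param poly two-column vertex matrix.
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Ray-casting point-in-polygon test (boundary points count as inside)
#' @param x,y coordinate vectors.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # exactly on the segment?
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- (x >= pmin(xi, xj) - 1e-9) & (x <= pmax(xi, xj) + 1e-9) &
      (y >= pmin(yi, yj) - 1e-9) & (y <= pmax(yi, yj) + 1e-9)
    on_edge <- on_edge | (abs(cross) < 1e-6 & within)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Construct a marked cell point pattern
#'
#' @param cells data frame with columns `cell_id`, `x`, `y` (micrometers),
#'   `phenotype`, `tissue_category`. Row order is preserved and defines
#'   deterministic tie-breaking downstream.
#' @param roi a [roi()] object, or a bare positive number taken as the ROI
#'   area in mm^2.
#' @param patient_id identifier.
#' @param outcome one of good, poor, normal, unlabeled.
#' @param validate run invariant checks (default TRUE).
#' @return object of class `til_pattern`: list(patient_id, outcome, cells, roi).
#' @export
til_pattern <- function(cells, roi, patient_id = "patient", outcome = "unlabeled",
                        validate = TRUE) {
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "x", "y", "phenotype", "tissue_category")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stop("cells is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cells <- cells[required]
  cells$cell_id <- as.character(cells$cell_id)
  cells$x <- as.numeric(cells$x)
  cells$y <- as.numeric(cells$y)
  cells$phenotype <- as.character(cells$phenotype)
  cells$tissue_category <- as.character(cells$tissue_category)
  rownames(cells) <- NULL
  if (is.numeric(roi)) roi <- roi(area_mm2 = roi)
  if (!inherits(roi, "til_roi")) stop("roi must be a til_roi or a numeric area",
                                      call. = FALSE)
  outcome <- match.arg(outcome, OUTCOME_LEVELS)
  pat <- structure(
    list(patient_id = as.character(patient_id), outcome = outcome,
         cells = cells, roi = roi),
    class = "til_pattern"
  )
  if (validate) {
    rep <- validate_pattern(pat)
    if (length(rep$violations) > 0)
      stop("invalid pattern: ", paste(rep$violations, collapse = "; "),
           call. = FALSE)
  }
  pat
}

#' @export
print.til_pattern <- function(x, ...) {
  cat(sprintf("<til_pattern> patient %s (%s): %d cells (%d lymphocytes), ROI %.4g mm^2\n",
              x$patient_id, x$outcome, nrow(x$cells),
              sum(is_lymphocyte(x$cells$phenotype)), x$roi$area_mm2))
  invisible(x)
}

#' Validate a pattern against the type invariants
#'
#' Returns a report rather than signalling: hard violations (non-finite
#' coordinates, unknown enum levels, duplicate ids, cells outside the ROI
#' boundary, inconsistent ROI area) versus warnings (duplicate coordinates,
#' which can legitimately occur at digitization resolution; bounding-box ROI
#' fallback).
#'
#' @param pattern a `til_pattern`.
#' @return list with character vectors `violations` and `warnings`; both empty
#'   iff all invariants hold.
#' @export
validate_pattern <- function(pattern) {
  v <- character(0); w <- character(0)
  cells <- pattern$cells
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    v <- c(v, "non-finite coordinates")
  bad_ph <- setdiff(unique(cells$phenotype), PHENOTYPE_LEVELS)
  if (length(bad_ph) > 0)
    v <- c(v, paste0("unknown phenotype level(s): ", paste(bad_ph, collapse = ", ")))
  bad_tc <- setdiff(unique(cells$tissue_category), TISSUE_LEVELS)
  if (length(bad_tc) > 0)
    v <- c(v, paste0("unknown tissue category level(s): ", paste(bad_tc, collapse = ", ")))
  if (anyDuplicated(cells$cell_id) > 0)
    v <- c(v, "duplicate cell_id values")
  if (!is.null(pattern$roi$boundary) && nrow(cells) > 0 &&
      all(is.finite(cells$x)) && all(is.finite(cells$y))) {
    inside <- point_in_polygon(cells$x, cells$y, pattern$roi$boundary)
    if (!all(inside))
      v <- c(v, sprintf("%d cell(s) outside the ROI boundary", sum(!inside)))
  }
  if (anyDuplicated(cells[c("x", "y")]) > 0)
    w <- c(w, "duplicate coordinates (cells sharing a centroid)")
  if (isTRUE(attr(pattern$roi, "bbox_fallback")))
    w <- c(w, "ROI area defaulted to the cell bounding box")
  list(violations = v, warnings = w)
}

#' Read a pattern from a delimited table
#'
#' Expects a header with (configurable) columns for cell id, x, y, phenotype
#' and tissue category; coordinates in micrometers. Raw phenotype/tissue labels
#' are normalized through alias tables; unmappable labels are an error naming
#' the offending rows. If no ROI area or polygon is supplied the area of the
#' cell bounding box is used and flagged in the validation report.
#'
#' @param path CSV (`,`) or TSV (`\t`, for `.tsv`/`.txt`) file.
#' @param roi_area_mm2 optional ROI area in mm^2.
#' @param boundary_path optional ROI polygon file (GeoJSON `.geojson`/`.json`
#'   or WKT text); defaults to a `<path-sans-ext>.roi.geojson` sidecar when one
#'   exists.
#' @param patient_id,outcome pattern metadata.
#' @param columns named character vector mapping the canonical names
#'   (`cell_id`, `x`, `y`, `phenotype`, `tissue_category`) to header names.
#' @param phenotype_map,tissue_map alias tables (lowercased label -> level).
#' @return a validated `til_pattern`.
#' @export
read_pattern_table <- function(path, roi_area_mm2 = NULL, boundary_path = NULL,
                               patient_id = NULL, outcome = "unlabeled",
                               columns = c(cell_id = "cell_id", x = "x_um",
                                           y = "y_um", phenotype = "phenotype",
                                           tissue_category = "tissue_category"),
                               phenotype_map = default_phenotype_map(),
                               tissue_map = default_tissue_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty pattern table: ", path, call. = FALSE)
  need <- unname(columns[c("cell_id", "x", "y", "phenotype", "tissue_category")])
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cells <- data.frame(
    cell_id = as.character(tab[[columns[["cell_id"]]]]),
    x = as.numeric(tab[[columns[["x"]]]]),
    y = as.numeric(tab[[columns[["y"]]]]),
    phenotype = normalize_labels(tab[[columns[["phenotype"]]]], phenotype_map,
                                 "phenotype"),
    tissue_category = normalize_labels(tab[[columns[["tissue_category"]]]],
                                       tissue_map, "tissue category"),
    stringsAsFactors = FALSE
  )
  if (is.null(boundary_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), ".roi.geojson")
    if (file.exists(cand)) boundary_path <- cand
  }
  boundary <- if (!is.null(boundary_path)) read_roi_boundary(boundary_path) else NULL
  fallback <- FALSE
  if (is.null(roi_area_mm2) && is.null(boundary)) {
    roi_area_mm2 <- max(diff(range(cells$x)) * diff(range(cells$y)), .Machine$double.eps) / 1e6
    fallback <- TRUE
  }
  r <- roi(area_mm2 = roi_area_mm2, boundary = boundary)
  if (fallback) attr(r, "bbox_fallback") <- TRUE
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  til_pattern(cells, r, patient_id = patient_id, outcome = outcome)
}

#' Write a pattern to a delimited table
#'
#' Emits a CSV/TSV readable by [read_pattern_table()] with numeric fields at
#' full double precision; a polygon ROI, when present, is written to a
#' `<path-sans-ext>.roi.geojson` sidecar.
#'
#' @param pattern a valid `til_pattern`.
#' @param path output file; `.tsv`/`.txt` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(pattern, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(
    cell_id = pattern$cells$cell_id,
    x_um = sprintf("%.10g", pattern$cells$x),
    y_um = sprintf("%.10g", pattern$cells$y),
    phenotype = pattern$cells$phenotype,
    tissue_category = pattern$cells$tissue_category,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write pattern table to ", path, call. = FALSE)
  if (!is.null(pattern$roi$boundary)) {
    write_roi_boundary(pattern$roi$boundary,
                       paste0(sub("\\.[^.]*$", "", path), ".roi.geojson"))
  }
  invisible(path)
}

#' Read an ROI polygon from GeoJSON or WKT text
#' @param path `.geojson`/`.json` (GeoJSON Polygon) or a WKT `POLYGON ((...))` file.
#' @return two-column vertex matrix in micrometers.
#' @export
read_roi_boundary <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    coords <- if (!is.null(g$coordinates)) g$coordinates else g$geometry$coordinates
    if (is.array(coords) && length(dim(coords)) == 3) {
      ring <- coords[1, , ]
    } else {
      if (is.list(coords)) coords <- coords[[1]]
      ring <- if (is.matrix(coords)) coords
      else matrix(unlist(coords), ncol = 2, byrow = TRUE)
    }
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = " ")
    body <- sub(".*POLYGON\\s*\\(\\(", "", txt, ignore.case = TRUE)
    body <- sub("\\)\\).*", "", body)
    pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    ring <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  }
  # drop a repeated closing vertex
  n <- nrow(ring)
  if (n > 3 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  storage.mode(ring) <- "double"
  ring
}

write_roi_boundary <- function(boundary, path) {
  ring <- rbind(boundary, boundary[1, , drop = FALSE])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)),
                                        function(i) c(ring[i, 1], ring[i, 2]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a deposited list of spatstat `ppp` patterns to pattern tables
#'
#' One-script converter for serialized marked point-pattern lists (RDS holding
#' a list of `ppp`-like objects with marks `Tissue.Category` and `Phenotype`
#' and coordinates in micrometers). The `ppp` structure is accessed as a plain
#' list (`$x`, `$y`, `$marks`, `$window`), so the spatstat package itself is
#' not required to unpack it. Mark levels are introspected and normalized
#' through the alias tables; unmapped levels raise an error listing them so the
#' map can be extended.
#'
#' @param rds_path path to the RDS file.
#' @param out_dir directory for one CSV per patient.
#' @param outcomes optional character vector of outcome labels, one per pattern.
#' @param phenotype_map,tissue_map alias tables as in [read_pattern_table()].
#' @return character vector of written CSV paths, invisibly.
#' @export
read_deposited_patterns <- function(rds_path, out_dir,
                                    outcomes = NULL,
                                    phenotype_map = default_phenotype_map(),
                                    tissue_map = default_tissue_map()) {
  pats <- readRDS(rds_path)
  if (!is.list(pats)) stop("expected an RDS list of point patterns", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(pats)
  if (is.null(ids)) ids <- sprintf("patient_%02d", seq_along(pats))
  paths <- character(length(pats))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    marks <- as.data.frame(p$marks)
    ph_col <- grep("^phenotype$", names(marks), ignore.case = TRUE, value = TRUE)
    tc_col <- grep("tissue", names(marks), ignore.case = TRUE, value = TRUE)
    if (length(ph_col) != 1 || length(tc_col) < 1)
      stop("pattern ", ids[i], ": cannot locate Phenotype/Tissue.Category marks",
           call. = FALSE)
    cells <- data.frame(
      cell_id = sprintf("c%06d", seq_along(p$x)),
      x = as.numeric(p$x), y = as.numeric(p$y),
      phenotype = normalize_labels(marks[[ph_col]], phenotype_map, "phenotype"),
      tissue_category = normalize_labels(marks[[tc_col[1]]], tissue_map,
                                         "tissue category"),
      stringsAsFactors = FALSE
    )
    area_mm2 <- ppp_window_area_um2(p$window) / 1e6
    out <- file.path(out_dir, paste0(ids[i], ".csv"))
    pat <- til_pattern(cells, roi(area_mm2 = area_mm2), patient_id = ids[i],
                       outcome = if (is.null(outcomes)) "unlabeled" else outcomes[i])
    write_pattern_table(pat, out)
    paths[i] <- out
  }
  invisible(paths)
}

# Area of a ppp observation window (rectangle, polygonal, or pixel mask)
# accessed structurally, in square micrometers.
ppp_window_area_um2 <- function(win) {
  if (is.null(win)) stop("pattern has no observation window", call. = FALSE)
  type <- win$type
  if (identical(type, "rectangle") || (is.null(type) && !is.null(win$xrange)))
    return(diff(win$xrange) * diff(win$yrange))
  if (identical(type, "polygonal"))
    return(sum(vapply(win$bdry, function(b)
      polygon_area(cbind(b$x, b$y)), numeric(1))))
  if (identical(type, "mask")) {
    px <- diff(win$xrange) / ncol(win$m)
    py <- diff(win$yrange) / nrow(win$m)
    return(sum(win$m) * px * py)
  }
  stop("unsupported window type: ", type, call. = FALSE)
}
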