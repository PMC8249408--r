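# Multiscale grid statistics: occupancy and box-counting fractal dimensions.
#
# The tissue is tiled with half-open squares of side L anchored at the ROI
# bounding-box minimum. Each square is scored 0/1 by a binary question
# ("is there at least one B cell in the square?"); squares with no cells at
# all are omitted from the denominator because they lie outside the tissue.
# n(L) counts squares scoring 1, N(L) squares containing any cell, and the
# occupancy is n/N. The fractal dimension at a scale window is the
# least-squares slope of ln n(L) versus ln(1/L) (natural logs); the FD
# difference is the large-scale slope minus the small-scale slope.

#' Default ladder of square sides (micrometers)
#'
#' Thirteen geometrically spaced values spanning 10-600 um. Members <= 40 um
#' form the default small-scale fit window, members >= 200 um the large-scale
#' window.
#' @return numeric vector.
#' @export
default_L_ladder <- function() c(10, 14, 20, 28, 40, 57, 80, 113, 160, 226, 320, 453, 600)

#' A binary question asked of every grid square
#'
#' @param phenotypes character vector of phenotype levels; `"T"` expands to all
#'   CD3+ T lineage levels and `"lymphocyte"` to all lymphocyte levels.
#' @param tissue_scope `any`, `cancer_island` or `stroma`.
#' @param membership_scope `any`, `isolated_only`, `in_lc_only`,
#'   `in_heterotypic_lc` or `in_pure_t_lc`; scopes other than `any` require the
#'   pattern to carry cluster annotations (see [annotate_membership()]).
#' @return object of class `binary_question`.
#' @export
binary_question <- function(phenotypes, tissue_scope = "any",
                            membership_scope = "any") {
  if (length(phenotypes) == 0) stop("phenotypes must be non-empty", call. = FALSE)
  tissue_scope <- match.arg(tissue_scope, c("any", "cancer_island", "stroma"))
  membership_scope <- match.arg(
    membership_scope,
    c("any", "isolated_only", "in_lc_only", "in_heterotypic_lc", "in_pure_t_lc")
  )
  structure(list(phenotypes = expand_phenotypes(phenotypes),
                 tissue_scope = tissue_scope,
                 membership_scope = membership_scope),
            class = "binary_question")
}

expand_phenotypes <- function(phenotypes) {
  out <- character(0)
  for (p in phenotypes) {
    out <- c(out, switch(p,
      "lymphocyte" = LYMPHOCYTE_PHENOTYPES,
      "T" = T_LINEAGE_PHENOTYPES,
      p
    ))
  }
  bad <- setdiff(out, PHENOTYPE_LEVELS)
  if (length(bad) > 0)
    stop("unknown phenotype(s) in question: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unique(out)
}

#' Which cells satisfy a binary question?
#'
#' @param pattern a `til_pattern` (annotated if the question uses a membership
#'   scope).
#' @param question a [binary_question()].
#' @return logical vector over the pattern's cells.
#' @export
cells_matching <- function(pattern, question) {
  cells <- pattern$cells
  ok <- cells$phenotype %in% question$phenotypes
  if (question$tissue_scope != "any")
    ok <- ok & cells$tissue_category == question$tissue_scope
  if (question$membership_scope != "any") {
    if (is.null(cells$in_lc))
      stop("membership-scoped question requires a pattern annotated with ",
           "annotate_membership()", call. = FALSE)
    ok <- ok & switch(question$membership_scope,
      isolated_only = is_lymphocyte(cells$phenotype) & !cells$in_lc,
      in_lc_only = cells$in_lc,
      in_heterotypic_lc = cells$in_lc & !is.na(cells$lc_type) &
        cells$lc_type == "heterotypic",
      in_pure_t_lc = cells$in_lc & !is.na(cells$lc_type) &
        cells$lc_type == "pure_T"
    )
  }
  ok
}

# Grid geometry shared by every overlay: origin at the ROI bounding-box
# minimum; half-open squares; cells exactly on the maximal edge are clamped
# into the last row/column.
grid_frame <- function(pattern, origin = NULL) {
  if (!is.null(pattern$roi$boundary)) {
    bx <- range(pattern$roi$boundary[, 1])
    by <- range(pattern$roi$boundary[, 2])
  } else {
    bx <- range(pattern$cells$x)
    by <- range(pattern$cells$y)
  }
  if (!is.null(origin)) {
    bx[1] <- origin[1]; by[1] <- origin[2]
  }
  list(x0 = bx[1], y0 = by[1], x1 = bx[2], y1 = by[2])
}

#' Overlay one grid and count squares
#'
#' @param pattern a non-empty `til_pattern`.
#' @param L square side in micrometers.
#' @param question a [binary_question()].
#' @param origin optional grid anchor `(x, y)`; default is the ROI bounding-box
#'   minimum.
#' @param denominator `"cells"` counts toward N only squares containing at
#'   least one cell of any type (the tissue-omission rule); `"window"` counts
#'   every square intersecting the ROI bounding box (for simulated reference
#'   patterns with no tissue to delimit).
#' @return list with `n`, `N` and `occupancy = n/N`.
#' @export
overlay_counts <- function(pattern, L, question, origin = NULL,
                           denominator = c("cells", "window")) {
  denominator <- match.arg(denominator)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  cells <- pattern$cells
  if (nrow(cells) == 0) stop("pattern has no cells (N would be 0)", call. = FALSE)
  g <- grid_frame(pattern, origin)
  nx <- max(1L, as.integer(ceiling((g$x1 - g$x0) / L - 1e-9)))
  ny <- max(1L, as.integer(ceiling((g$y1 - g$y0) / L - 1e-9)))
  ix <- pmin(pmax(floor((cells$x - g$x0) / L), 0), nx - 1L)
  iy <- pmin(pmax(floor((cells$y - g$y0) / L), 0), ny - 1L)
  key <- ix + nx * iy
  N <- if (denominator == "window") as.numeric(nx) * ny
  else length(unique(key))
  match_cell <- cells_matching(pattern, question)
  n <- length(unique(key[match_cell]))
  list(n = n, N = N, occupancy = n / N)
}

#' Occupancy as a function of square size
#'
#' @inheritParams overlay_counts
#' @param Ls positive square sides, micrometers.
#' @return data frame of class `box_count_curve` with columns `L`, `n`, `N`,
#'   `occupancy`, sorted by increasing `L`.
#' @export
occupancy_curve <- function(pattern, Ls = default_L_ladder(), question,
                            origin = NULL, denominator = c("cells", "window")) {
  denominator <- match.arg(denominator)
  if (length(Ls) == 0 || any(Ls <= 0))
    stop("Ls must be a non-empty vector of positive sides", call. = FALSE)
  Ls <- sort(unique(Ls))
  rows <- lapply(Ls, function(L)
    overlay_counts(pattern, L, question, origin, denominator))
  out <- data.frame(
    L = Ls,
    n = vapply(rows, `[[`, numeric(1), "n"),
    N = vapply(rows, `[[`, numeric(1), "N"),
    occupancy = vapply(rows, `[[`, numeric(1), "occupancy")
  )
  class(out) <- c("box_count_curve", "data.frame")
  out
}

#' Area under an occupancy curve
#'
#' Trapezoidal integral of occupancy against ln(L) (scale-free across the
#' 60-fold range of L); a linear-L abscissa is available as an option.
#'
#' @param curve a [occupancy_curve()] result with at least 2 entries.
#' @param abscissa `"log"` (default) or `"linear"`.
#' @return scalar area.
#' @export
occupancy_auc <- function(curve, abscissa = c("log", "linear")) {
  abscissa <- match.arg(abscissa)
  if (nrow(curve) < 2) stop("need >= 2 curve entries", call. = FALSE)
  x <- if (abscissa == "log") log(curve$L) else curve$L
  y <- curve$occupancy
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Least-squares slope of ln n versus ln(1/L) restricted to a scale window.
fit_fd_curve <- function(curve, scale_window, normalized = FALSE) {
  sel <- curve$L >= scale_window[1] & curve$L <= scale_window[2]
  sub <- curve[sel, , drop = FALSE]
  yval <- if (normalized) sub$n / sub$N else sub$n
  keep <- yval > 0
  sub <- sub[keep, , drop = FALSE]
  yval <- yval[keep]
  if (nrow(sub) < 3)
    stop(sprintf("insufficient data: %d usable L values in window [%g, %g]",
                 nrow(sub), scale_window[1], scale_window[2]), call. = FALSE)
  x <- log(1 / sub$L)
  y <- log(yval)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(scale_window = scale_window,
         slope_s = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = nrow(sub)),
    class = "fd_fit"
  )
}

#' Box-counting fractal dimension over a scale window
#'
#' Fits the least-squares slope of ln n(L) versus ln(1/L) using the L-ladder
#' members inside `scale_window`; L values with n(L) = 0 are dropped and at
#' least three must remain. The un-normalized n(L) is used by default; the
#' N(L)-normalized variant (used for plotting curves across images of
#' different sizes) is available via `normalized = TRUE` and has the same
#' slope whenever N(L) follows the window geometry exactly.
#'
#' @inheritParams occupancy_curve
#' @param scale_window `(L_min, L_max)` in micrometers.
#' @param normalized fit ln(n/N) instead of ln(n).
#' @return object of class `fd_fit` with `slope_s`, `intercept`, `r_squared`,
#'   `scale_window`, `n_points`.
#' @export
fit_fractal_dimension <- function(pattern, question, Ls = default_L_ladder(),
                                  scale_window = c(200, 600),
                                  normalized = FALSE, origin = NULL,
                                  denominator = c("cells", "window")) {
  curve <- occupancy_curve(pattern, Ls, question, origin, denominator)
  fit_fd_curve(curve, scale_window, normalized)
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> window [%g, %g] um: slope %.4f (R^2 %.3f, %d points)\n",
              x$scale_window[1], x$scale_window[2], x$slope_s, x$r_squared,
              x$n_points))
  invisible(x)
}

#' Fractal-dimension difference between large and small scales
#'
#' `delta_s = s_large - s_small`, the large-scale slope minus the small-scale
#' slope. Large values indicate spatially dispersed cells (area-filling at
#' large scales, point-like at small scales); values near zero indicate a
#' scale-free, near-fractal arrangement.
#'
#' @inheritParams fit_fractal_dimension
#' @param Ls_small,Ls_large ladder members for the two fits; defaults are the
#'   members of [default_L_ladder()] at 10-40 um and 200-600 um.
#' @return object of class `fd_difference` with `s_small`, `s_large`
#'   ([fit_fractal_dimension()] objects) and `delta_s`.
#' @export
fd_difference <- function(pattern, question,
                          Ls_small = NULL, Ls_large = NULL,
                          normalized = FALSE, origin = NULL,
                          denominator = c("cells", "window")) {
  ladder <- default_L_ladder()
  if (is.null(Ls_small)) Ls_small <- ladder[ladder <= 40]
  if (is.null(Ls_large)) Ls_large <- ladder[ladder >= 200]
  fs <- fit_fractal_dimension(pattern, question, Ls_small, range(Ls_small),
                              normalized, origin, denominator)
  fl <- fit_fractal_dimension(pattern, question, Ls_large, range(Ls_large),
                              normalized, origin, denominator)
  structure(list(s_small = fs, s_large = fl,
                 delta_s = fl$slope_s - fs$slope_s),
            class = "fd_difference")
}

#' @export
print.fd_difference <- function(x, ...) {
  cat(sprintf("<fd_difference> s_large %.4f - s_small %.4f = delta_s %.4f\n",
              x$s_large$slope_s, x$s_small$slope_s, x$delta_s))
  invisible(x)
}
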