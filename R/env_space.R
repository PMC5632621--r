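#' Principal component analysis of the whole environmental background
#'
#' Fits a PCA on the environmental values of every background cell of the
#' study area ("PCA-env"), with variables centred and scaled to unit variance
#' internally. All axes are returned; downstream niche analysis uses the
#' first two. Explained variance fractions are sorted decreasing and sum to
#' one over all axes.
#'
#' @param background_env cells x variables data frame or matrix.
#' @return an object of class `pca_env` with elements `loadings`
#'   (variables x axes), `explained` (fraction per axis), `center`, `scale`
#'   and `variables`.
#' @export
fit_pca_env <- function(background_env) {
  m <- as.matrix(background_env)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) abort("Need at least 3 background cells.")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    abort(paste0("Constant variable(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  structure(
    list(loadings = pc$rotation,
         explained = pc$sdev^2 / sum(pc$sdev^2),
         center = pc$center, scale = pc$scale,
         variables = colnames(m)),
    class = "pca_env"
  )
}

#' @export
print.pca_env <- function(x, ...) {
  cat("<pca_env> ", length(x$variables), " variables\n", sep = "")
  cat("  axis 1: ", round(100 * x$explained[1], 2), "% of variance\n", sep = "")
  if (length(x$explained) > 1)
    cat("  axis 2: ", round(100 * x$explained[2], 2), "% of variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.pca_env <- function(x, ...) {
  tibble(
    variable = rep(x$variables, times = ncol(x$loadings)),
    axis = rep(seq_len(ncol(x$loadings)), each = length(x$variables)),
    loading = as.vector(x$loadings)
  )
}

#' @export
glance.pca_env <- function(x, ...) {
  tibble(axis = seq_along(x$explained), explained_fraction = x$explained)
}

#' Project environments onto the first two ordination axes
#'
#' @param env data frame or matrix of environmental values with one column
#'   per model variable (order and names must match the fitted model).
#' @param model a [fit_pca_env()] model.
#' @return a two-column matrix of axis-1/axis-2 scores.
#' @export
project_env <- function(env, model) {
  m <- as.matrix(env)
  if (!is.null(colnames(m))) {
    if (!all(model$variables %in% colnames(m)))
      abort("`env` lacks some model variables.")
    m <- m[, model$variables, drop = FALSE]
  } else if (ncol(m) != length(model$variables)) {
    abort(paste0("`env` has ", ncol(m), " columns; model expects ",
                 length(model$variables), "."))
  }
  z <- sweep(sweep(m, 2L, model$center), 2L, model$scale, `/`)
  s <- z %*% model$loadings[, 1:2, drop = FALSE]
  colnames(s) <- c("axis1", "axis2")
  s
}

# Per-axis normal-reference (Silverman) bandwidths on the background scores,
# in the 4*sd convention MASS::kde2d expects (kde2d divides h by 4).
nrd_bandwidths <- function(bg_scores) {
  h <- c(MASS::bandwidth.nrd(bg_scores[, 1]),
         MASS::bandwidth.nrd(bg_scores[, 2]))
  if (any(h <= 0)) abort("Degenerate background: zero bandwidth on an axis.")
  h
}

# Kernel density surface of a score cloud on a fixed R x R grid.
# Returns the density matrix (rows = axis1 cells, cols = axis2 cells).
kernel_surface <- function(scores, bounds, h, R) {
  d <- MASS::kde2d(scores[, 1], scores[, 2], h = h, n = R,
                   lims = c(bounds$x, bounds$y))
  d$z
}

occupancy_from_density <- function(o, e, mode) {
  if (mode == "uncorrected") {
    z <- o / max(o)
  } else {
    ratio <- matrix(0, nrow(o), ncol(o))
    pos <- e > 0
    ratio[pos] <- o[pos] / e[pos]
    z <- ratio / max(ratio)
  }
  z
}

#' Kernel-smoothed occupancy grid in environment space
#'
#' Discretises the plane of the first two ordination axes into an `R` x `R`
#' grid bounded by the background scores (expanded by a margin) and evaluates
#' Gaussian product-kernel densities of the occurrences (`o`) and of the
#' background (`e`) at the cell centers. Bandwidths follow the per-axis
#' normal-reference rule computed on the *background* and are reused for the
#' occurrence density so the two surfaces are comparable. Occupancy is
#' `z = o / max(o)` (`uncorrected`, default) or `z = (o/e) / max(o/e)` over
#' cells with `e > 0` (`corrected`); `p = z / sum(z)` is the normalised
#' occupancy entering overlap and breadth statistics.
#'
#' Occurrence scores outside the background bounds are clipped to the
#' boundary cell and counted in attribute `n_clipped`.
#'
#' @param occ_scores two-column matrix of occurrence scores.
#' @param background_scores two-column matrix of background scores (>= 10).
#' @param R grid resolution per axis (default 100).
#' @param mode `"uncorrected"` or `"corrected"`.
#' @param margin fractional expansion of the background range per axis.
#' @param bounds,h optional pre-computed bounds / bandwidths (used by the
#'   randomization tests so every replicate shares the observed grid).
#' @return an object of class `env_space_grid`.
#' @export
build_grid <- function(occ_scores, background_scores, R = 100,
                       mode = c("uncorrected", "corrected"),
                       margin = 0.05, bounds = NULL, h = NULL) {
  mode <- match.arg(mode)
  occ_scores <- as.matrix(occ_scores)
  background_scores <- as.matrix(background_scores)
  if (nrow(occ_scores) < 1L) abort("Need at least one occurrence score.")
  if (nrow(background_scores) < 10L) abort("Need at least 10 background scores.")
  if (R < 10L) abort("Grid resolution R must be at least 10.")
  if (is.null(bounds)) bounds <- grid_bounds(background_scores, margin)
  if (is.null(h)) h <- nrd_bandwidths(background_scores)

  n_clipped <- sum(occ_scores[, 1] < bounds$x[1] | occ_scores[, 1] > bounds$x[2] |
                     occ_scores[, 2] < bounds$y[1] | occ_scores[, 2] > bounds$y[2])
  if (n_clipped > 0L) {
    inform(paste0(n_clipped,
                  " occurrence score(s) outside the background bounds clipped."))
    occ_scores[, 1] <- pmin(pmax(occ_scores[, 1], bounds$x[1]), bounds$x[2])
    occ_scores[, 2] <- pmin(pmax(occ_scores[, 2], bounds$y[1]), bounds$y[2])
  }

  o <- kernel_surface(occ_scores, bounds, h, R)
  e <- kernel_surface(background_scores, bounds, h, R)
  z <- occupancy_from_density(o, e, mode)
  p <- z / sum(z)
  structure(
    list(R = R, mode = mode, bounds = bounds, h = h,
         x = seq(bounds$x[1], bounds$x[2], length.out = R),
         y = seq(bounds$y[1], bounds$y[2], length.out = R),
         o = o, e = e, z = z, p = p,
         n_occ = nrow(occ_scores), n_clipped = n_clipped),
    class = "env_space_grid"
  )
}

grid_bounds <- function(background_scores, margin = 0.05) {
  rx <- range(background_scores[, 1])
  ry <- range(background_scores[, 2])
  list(x = rx + c(-1, 1) * margin * diff(rx),
       y = ry + c(-1, 1) * margin * diff(ry))
}

# Fast path used inside randomization loops: only the occurrence surface is
# re-estimated; background density and the derived normalisation are reused.
occupancy_p <- function(scores, bounds, h, R, mode = "uncorrected", e = NULL) {
  o <- kernel_surface(as.matrix(scores), bounds, h, R)
  z <- if (mode == "uncorrected") o / max(o) else occupancy_from_density(o, e, mode)
  z / sum(z)
}

#' @export
print.env_space_grid <- function(x, ...) {
  cat("<env_space_grid> ", x$R, " x ", x$R, " cells, mode = ", x$mode,
      ", ", x$n_occ, " occurrence(s)\n", sep = "")
  invisible(x)
}

#' Tidy cell-level view of an environment-space grid
#'
#' @param x an `env_space_grid`.
#' @param ... unused.
#' @return tibble with `axis1`, `axis2`, `o`, `e`, `z`, `p` per cell.
#' @export
tidy.env_space_grid <- function(x, ...) {
  tibble(
    axis1 = rep(x$x, times = x$R),
    axis2 = rep(x$y, each = x$R),
    o = as.vector(x$o), e = as.vector(x$e),
    z = as.vector(x$z), p = as.vector(x$p)
  )
}

# Smallest density level whose superlevel set holds `frac` of total mass.
density_envelope_level <- function(e, frac) {
  v <- sort(as.vector(e), decreasing = TRUE)
  cum <- cumsum(v) / sum(v)
  v[which(cum >= frac)[1]]
}

#' Shaded density plot of a lineage's niche in environment space
#'
#' Gray-to-black shading shows the kernel-smoothed occurrence density;
#' dashed and solid contours enclose 50% and 100% of the available
#' (background) environment.
#'
#' @param object an `env_space_grid`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.env_space_grid <- function(object, ...) {
  cells <- tidy(object)
  lev50 <- density_envelope_level(object$e, 0.50)
  lev100 <- min(object$e[object$e > 0])
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 name = "occupancy") +
    ggplot2::geom_contour(ggplot2::aes(z = .data$e), breaks = lev50,
                          colour = "grey30", linetype = "dashed") +
    ggplot2::geom_contour(ggplot2::aes(z = .data$e), breaks = lev100,
                          colour = "grey30") +
    ggplot2::labs(x = "PCA axis 1", y = "PCA axis 2") +
    ggplot2::theme_minimal()
}
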