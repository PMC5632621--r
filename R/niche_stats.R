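#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` over the cells of two normalised occupancy
#' grids. `D` ranges from 0 (no shared environmental space) to 1 (identical
#' niches) and is symmetric in its arguments.
#'
#' @param p1,p2 normalised occupancy grids: matrices of identical shape, each
#'   summing to 1 (tolerance 1e-6), or `env_space_grid` objects (their `p`
#'   component is used).
#' @return the overlap `D`, a number in `[0, 1]`.
#' @export
schoener_d <- function(p1, p2) {
  p1 <- grid_p(p1); p2 <- grid_p(p2)
  if (!identical(dim(p1), dim(p2)))
    abort("Occupancy grids have different shapes.")
  if (abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6)
    abort("Occupancy grids must each sum to 1 (tolerance 1e-6).")
  1 - 0.5 * sum(abs(p1 - p2))
}

grid_p <- function(x) {
  if (inherits(x, "env_space_grid")) x$p else as.matrix(x)
}

#' Levins' inverse-concentration niche breadth
#'
#' `B = 1 / sum(p^2)` — the effective number of environment-space cells a
#' lineage occupies; `B_norm = (B - 1) / (ncells - 1)` rescales it to
#' `[0, 1]`.
#'
#' @param p a normalised occupancy grid or `env_space_grid`.
#' @return tibble with columns `B` and `B_norm`.
#' @export
levins_breadth <- function(p) {
  p <- grid_p(p)
  if (sum(p) == 0) abort("All-zero occupancy grid.")
  if (abs(sum(p) - 1) > 1e-6)
    abort("Occupancy grid must sum to 1 (tolerance 1e-6).")
  B <- 1 / sum(p^2)
  tibble(B = B, B_norm = (B - 1) / (length(p) - 1))
}

#' Niche equivalency test
#'
#' Asks whether two occurrence sets are interchangeable in environment
#' space. The observed overlap `D` is compared with a null distribution
#' obtained by pooling both sets of scores and randomly repartitioning them
#' into pseudo-groups of the original sizes, rebuilding each occupancy grid
#' (with the bounds and bandwidths of the observed analysis) and recomputing
#' `D`. The test is one-tailed: equivalency is rejected when the observed
#' `D` is significantly *lower* than the null overlaps,
#' `p = (1 + #\{D_null <= D_obs\}) / (reps + 1)`.
#'
#' @param occ_a,occ_b two-column score matrices for the two lineages (>= 5
#'   rows each).
#' @param background_scores two-column background score matrix defining grid
#'   bounds and bandwidths.
#' @param reps number of null replicates (default 100).
#' @param R grid resolution.
#' @param alpha significance level for the verdict.
#' @param seed optional integer seed (local RNG state).
#' @param grid_fun optional function `scores -> normalised grid`; overrides
#'   the kernel grid machinery (used for exact small-space oracles).
#' @return tibble with `D`, `equivalency_p`, `equivalent` verdict and the
#'   null distribution in the list column `null_D`.
#' @export
equivalency_test <- function(occ_a, occ_b, background_scores, reps = 100,
                             R = 100, alpha = 0.05, seed = NULL,
                             grid_fun = NULL) {
  if (reps < 1) abort("`reps` must be at least 1.")
  occ_a <- as.matrix(occ_a); occ_b <- as.matrix(occ_b)
  if (is.null(grid_fun)) {
    if (nrow(occ_a) < 5L || nrow(occ_b) < 5L)
      abort("Each lineage needs at least 5 occurrences.")
    bounds <- grid_bounds(as.matrix(background_scores))
    h <- nrd_bandwidths(as.matrix(background_scores))
    grid_fun <- function(s) occupancy_p(s, bounds, h, R)
  }
  d_obs <- schoener_d(grid_fun(occ_a), grid_fun(occ_b))
  pooled <- rbind(occ_a, occ_b)
  n_a <- nrow(occ_a); n <- nrow(pooled)
  null_d <- with_local_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n_a)
      schoener_d(grid_fun(pooled[idx, , drop = FALSE]),
                 grid_fun(pooled[-idx, , drop = FALSE]))
    }, numeric(1))
  })
  p <- (1 + sum(null_d <= d_obs)) / (reps + 1)
  tibble(D = d_obs, equivalency_p = p,
         equivalent = ifelse(p < alpha, "Different", "ns"),
         null_D = list(null_d))
}

#' Niche similarity test (directional)
#'
#' Asks whether the niche of lineage `b` is more similar to (or more
#' different from) the niche of lineage `a` than expected given the
#' environments available to `b`. The null preserves the *shape* of `b`'s
#' occurrence density: `b`'s scores are rigidly shifted so their centroid
#' lands on a point drawn uniformly from the bounding envelope of `b`'s
#' background scores (clipped to the analysis bounds), the occupancy grid is
#' rebuilt, and `D` against `a`'s observed grid is recomputed. Two one-sided
#' probabilities are returned:
#' `p_similar = (1 + #\{D_null >= D_obs\})/(reps+1)` and
#' `p_different = (1 + #\{D_null <= D_obs\})/(reps+1)`.
#'
#' @param grid_a `env_space_grid` (or normalised grid matrix) of lineage `a`.
#' @param occ_b two-column score matrix of lineage `b`.
#' @param background_b two-column score matrix of the background available
#'   to `b` (defines the envelope of candidate centroids).
#' @param reps,R,alpha,seed as in [equivalency_test()].
#' @param bounds,h optional grid geometry; defaults to the geometry stored
#'   in `grid_a` when it is an `env_space_grid`.
#' @param resample_points logical; if `TRUE`, the null instead resamples
#'   `nrow(occ_b)` scores uniformly from `b`'s background envelope (a
#'   point-resampling variant of the null).
#' @param mode occupancy mode used when rebuilding grids.
#' @param e background density surface (required for `mode = "corrected"`).
#' @return tibble with `D`, `similarity_p_similar`, `similarity_p_different`,
#'   `verdict` and the null distribution in list column `null_D`.
#' @export
similarity_test <- function(grid_a, occ_b, background_b, reps = 100, R = 100,
                            alpha = 0.05, seed = NULL, bounds = NULL,
                            h = NULL, resample_points = FALSE,
                            mode = "uncorrected", e = NULL) {
  if (reps < 1) abort("`reps` must be at least 1.")
  occ_b <- as.matrix(occ_b)
  background_b <- as.matrix(background_b)
  if (inherits(grid_a, "env_space_grid")) {
    bounds <- bounds %||% grid_a$bounds
    h <- h %||% grid_a$h
    R <- grid_a$R
  }
  if (is.null(bounds) || is.null(h))
    abort("Supply `bounds` and `h`, or pass an env_space_grid as `grid_a`.")
  p_a <- grid_p(grid_a)
  p_b_obs <- occupancy_p(occ_b, bounds, h, R, mode = mode, e = e)
  d_obs <- schoener_d(p_a, p_b_obs)
  env_x <- range(background_b[, 1])
  env_y <- range(background_b[, 2])
  centroid <- colMeans(occ_b)
  null_d <- with_local_seed(seed, {
    vapply(seq_len(reps), function(i) {
      if (resample_points) {
        s <- cbind(runif(nrow(occ_b), env_x[1], env_x[2]),
                   runif(nrow(occ_b), env_y[1], env_y[2]))
      } else {
        target <- c(runif(1, env_x[1], env_x[2]), runif(1, env_y[1], env_y[2]))
        s <- sweep(occ_b, 2L, centroid - target)
        s[, 1] <- pmin(pmax(s[, 1], bounds$x[1]), bounds$x[2])
        s[, 2] <- pmin(pmax(s[, 2], bounds$y[1]), bounds$y[2])
      }
      schoener_d(p_a, occupancy_p(s, bounds, h, R, mode = mode, e = e))
    }, numeric(1))
  })
  p_sim <- (1 + sum(null_d >= d_obs)) / (reps + 1)
  p_diff <- (1 + sum(null_d <= d_obs)) / (reps + 1)
  verdict <- if (p_sim < alpha) "Similar" else if (p_diff < alpha) "Different" else "ns"
  tibble(D = d_obs, similarity_p_similar = p_sim,
         similarity_p_different = p_diff, verdict = verdict,
         null_D = list(null_d))
}

#' Pairwise niche comparison of all lineages
#'
#' Runs the full comparison behind the classic niche-comparison table: for
#' every unordered pair of lineages, Schoener's `D` overlap, the
#' equivalency test, and both directions of the similarity test; plus
#' Levins' breadth per lineage. A single ordination fitted on the shared
#' background is used throughout, and every replicate grid reuses its
#' bounds and bandwidths.
#'
#' @param occurrences tibble with a `lineage` column and one column per
#'   environmental variable (e.g. the output of [extract_env()]).
#' @param background_env background cells x variables data frame (e.g.
#'   [env_background()] without the coordinate columns).
#' @param R grid resolution (default 100).
#' @param mode occupancy mode, `"uncorrected"` (default) or `"corrected"`.
#' @param reps randomization replicates per test (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed making all randomizations reproducible.
#' @param bonferroni if `TRUE`, verdicts use `alpha / n_pairs`.
#' @param variables optional character vector restricting the environmental
#'   variables used.
#' @return an object of class `niche_comparison_set`: a list with tibbles
#'   `comparisons` and `breadth`, the fitted `pca` model, and the per-lineage
#'   `grids`.
#' @export
compare_all <- function(occurrences, background_env, R = 100,
                        mode = c("uncorrected", "corrected"), reps = 100,
                        alpha = 0.05, seed = 1L, bonferroni = FALSE,
                        variables = NULL) {
  mode <- match.arg(mode)
  lineages <- sort(unique(occurrences$lineage))
  if (length(lineages) < 2L) abort("Need at least 2 lineages.")
  variables <- variables %||%
    setdiff(names(background_env), c("lon", "lat"))
  model <- fit_pca_env(background_env[variables])
  bg_scores <- project_env(background_env[variables], model)
  bounds <- grid_bounds(bg_scores)
  h <- nrd_bandwidths(bg_scores)
  e_surface <- kernel_surface(bg_scores, bounds, h, R)

  scores_by <- lapply(setNames(lineages, lineages), function(l) {
    s <- project_env(occurrences[occurrences$lineage == l, variables], model)
    # deterministic row order so results do not depend on input record order
    s[order(s[, 1], s[, 2]), , drop = FALSE]
  })
  grids <- lapply(scores_by, function(s)
    build_grid(s, bg_scores, R = R, mode = mode, bounds = bounds, h = h))

  breadth <- purrr::map_dfr(lineages, function(l) {
    mutate(levins_breadth(grids[[l]]), lineage = l, .before = 1)
  })

  pairs <- combn(lineages, 2L, simplify = FALSE)
  a_eff <- if (bonferroni) alpha / length(pairs) else alpha
  comparisons <- purrr::imap_dfr(pairs, function(pr, i) {
    a <- pr[1]; b <- pr[2]
    pair_seed <- if (is.null(seed)) NULL else seed + 1000L * i
    pfun <- function(s) occupancy_p(s, bounds, h, R, mode = mode, e = e_surface)
    eq <- equivalency_test(scores_by[[a]], scores_by[[b]], bg_scores,
                           reps = reps, R = R, alpha = a_eff,
                           seed = pair_seed, grid_fun = pfun)
    sim_ab <- similarity_test(grids[[a]], scores_by[[b]], bg_scores,
                              reps = reps, alpha = a_eff, mode = mode,
                              e = e_surface,
                              seed = if (is.null(pair_seed)) NULL else pair_seed + 1L)
    sim_ba <- similarity_test(grids[[b]], scores_by[[a]], bg_scores,
                              reps = reps, alpha = a_eff, mode = mode,
                              e = e_surface,
                              seed = if (is.null(pair_seed)) NULL else pair_seed + 2L)
    tibble(
      lineage_a = a, lineage_b = b, D = eq$D,
      similarity_ab_p = sim_ab$similarity_p_similar,
      similarity_ab_verdict = sim_ab$verdict,
      similarity_ba_p = sim_ba$similarity_p_similar,
      similarity_ba_verdict = sim_ba$verdict,
      equivalency_p = eq$equivalency_p,
      equivalency_verdict = eq$equivalent,
      null_equivalency = eq$null_D,
      null_similarity_ab = sim_ab$null_D,
      null_similarity_ba = sim_ba$null_D
    )
  })

  structure(
    list(comparisons = comparisons, breadth = breadth, pca = model,
         grids = grids, background_scores = bg_scores,
         e_surface = e_surface,
         params = list(R = R, mode = mode, reps = reps, alpha = alpha,
                       seed = seed, variables = variables)),
    class = "niche_comparison_set"
  )
}

#' @export
print.niche_comparison_set <- function(x, ...) {
  cat("<niche_comparison_set> ", nrow(x$breadth), " lineages, ",
      nrow(x$comparisons), " pairwise comparisons\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.niche_comparison_set <- function(x, ...) {
  select(x$comparisons, -dplyr::starts_with("null_"))
}

#' @export
glance.niche_comparison_set <- function(x, ...) {
  tibble(
    n_lineages = nrow(x$breadth),
    n_pairs = nrow(x$comparisons),
    pc1_explained = x$pca$explained[1],
    pc2_explained = x$pca$explained[2],
    R = x$params$R, reps = x$params$reps, alpha = x$params$alpha
  )
}

#' Write a niche-comparison table as CSV
#'
#' One row per unordered lineage pair: overlap `D`, both directional
#' similarity probabilities with verdicts, and the equivalency probability
#' with verdict. Null distributions can be dumped alongside for audit.
#'
#' @param x a `niche_comparison_set`.
#' @param path output CSV path.
#' @param dump_nulls if `TRUE`, a second CSV `<path>_nulls.csv` stores every
#'   replicate `D` value.
#' @export
write_comparison_csv <- function(x, path, dump_nulls = FALSE) {
  write.csv(tidy(x), path, row.names = FALSE)
  if (dump_nulls) {
    nulls <- x$comparisons |>
      select("lineage_a", "lineage_b", dplyr::starts_with("null_")) |>
      tidyr::pivot_longer(dplyr::starts_with("null_"),
                          names_to = "test", values_to = "null_D") |>
      tidyr::unnest("null_D") |>
      group_by(.data$lineage_a, .data$lineage_b, .data$test) |>
      mutate(replicate = row_number()) |>
      ungroup()
    write.csv(nulls, sub("\\.csv$", "_nulls.csv", path), row.names = FALSE)
  }
  invisible(path)
}

# Evaluate `expr` under a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
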