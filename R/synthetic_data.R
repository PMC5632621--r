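#' Synthetic spatially autocorrelated environmental rasters
#'
#' Generates standardized environmental layers by box-blurring white noise
#' (two passes, radius `smoothness` cells, clamped at the edges), which
#' yields smooth, spatially autocorrelated fields; `smoothness = 0` leaves
#' pure white noise. Pairwise correlation between chosen layers can be
#' injected by mixing. Seed-deterministic.
#'
#' @param n_vars number of layers (>= 2).
#' @param grid_dims `c(nrow, ncol)` cells.
#' @param smoothness smoothing radius in cells.
#' @param seed integer seed.
#' @param correlations optional list of `c(i, j, rho)` triples: layer `j`
#'   becomes `rho * layer_i + sqrt(1 - rho^2) * layer_j`.
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param names layer names (default `bio1..bioN`).
#' @return an [env_raster_stack()].
#' @export
make_env_rasters <- function(n_vars, grid_dims = c(100, 100), smoothness = 5,
                             seed = 1L, correlations = NULL,
                             extent = c(-10, 10, -10, 10), names = NULL) {
  if (n_vars < 2L) abort("Need at least 2 variables.")
  names <- names %||% paste0("bio", seq_len(n_vars))
  layers <- with_local_seed(seed, {
    lapply(seq_len(n_vars), function(i) {
      m <- matrix(rnorm(prod(grid_dims)), grid_dims[1], grid_dims[2])
      if (smoothness > 0) m <- box_blur(box_blur(m, smoothness), smoothness)
      (m - mean(m)) / sd(m)
    })
  })
  for (tr in correlations) {
    i <- tr[1]; j <- tr[2]; rho <- tr[3]
    m <- rho * layers[[i]] + sqrt(1 - rho^2) * layers[[j]]
    layers[[j]] <- (m - mean(m)) / sd(m)
  }
  env_raster_stack(setNames(layers, names),
                   xmin = extent[1], xmax = extent[2],
                   ymin = extent[3], ymax = extent[4])
}

# Running-mean blur along rows then columns with edge clamping.
box_blur <- function(m, radius) {
  k <- 2L * radius + 1L
  blur1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], radius), x, rep(x[n], radius))
    cs <- cumsum(c(0, xp))
    (cs[(k + 1):(n + k)] - cs[1:n]) / k
  }
  m <- apply(m, 1L, blur1)      # blur columns (returns transposed)
  t(apply(m, 1L, blur1))
}

#' Specification of a virtual lineage's niche
#'
#' Suitability is Gaussian in *environment* space (not geographic space):
#' `exp(-0.5 * (e - mu)' Sigma^-1 (e - mu))` for a cell with environment
#' `e`.
#'
#' @param label lineage id.
#' @param centroid niche optimum, one value per environmental variable.
#' @param covariance niche covariance matrix (symmetric positive-definite)
#'   or a single variance applied to all variables.
#' @param n sample size (>= 1).
#' @return a `lineage_spec` list.
#' @export
lineage_spec <- function(label, centroid, covariance, n) {
  if (n < 1) abort("`n` must be >= 1.")
  d <- length(centroid)
  if (length(covariance) == 1L) covariance <- diag(rep(covariance, d), d)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    abort("`covariance` must be symmetric positive-definite.")
  structure(list(label = label, centroid = centroid,
                 covariance = covariance, n = n),
            class = "lineage_spec")
}

#' Sample occurrence records for a virtual lineage
#'
#' Cells are sampled (with replacement) with probability proportional to the
#' Gaussian suitability of their environment under the lineage's niche
#' specification; coordinates are jittered uniformly within the cell.
#' The true suitability of each record's cell is attached for audit.
#'
#' @param spec a [lineage_spec()].
#' @param rasters an [env_raster_stack()].
#' @param seed integer seed.
#' @param years range of collection years sampled uniformly.
#' @return an occurrence tibble (`lineage`, `lon`, `lat`, `year`,
#'   `suitability`).
#' @export
sample_occurrences <- function(spec, rasters, seed = 1L,
                               years = c(1990L, 2020L)) {
  bg <- env_background(rasters)
  env <- as.matrix(bg[setdiff(names(bg), c("lon", "lat"))])
  if (ncol(env) != length(spec$centroid))
    abort("Centroid length must match the number of raster variables.")
  siginv <- solve(spec$covariance)
  d <- sweep(env, 2L, spec$centroid)
  q <- rowSums((d %*% siginv) * d)
  suit <- exp(-0.5 * q)
  if (!any(is.finite(q))) abort("Zero total suitability over the raster.")
  # sample on shifted log-suitability so narrow niches do not underflow
  prob <- exp(-0.5 * (q - min(q)))
  half <- rasters$cellsize / 2
  with_local_seed(seed, {
    idx <- sample.int(nrow(bg), spec$n, replace = TRUE, prob = prob)
    tibble(
      lineage = spec$label,
      lon = bg$lon[idx] + runif(spec$n, -half, half),
      lat = bg$lat[idx] + runif(spec$n, -half, half),
      year = sample(seq(years[1], years[2]), spec$n, replace = TRUE),
      suitability = suit[idx]
    )
  })
}

#' Simulate discrete characters under Mk1 on a fixed tree
#'
#' The root state is uniform over `1..k`; states evolve down each branch
#' with [mk1_transition()] probabilities. Ground-truth node states are
#' attached as attribute `node_states` (matrix nodes x characters).
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param alpha substitution rate (>= 0; 0 freezes evolution).
#' @param k number of states.
#' @param n_chars number of independent characters.
#' @param seed integer seed.
#' @return tibble `taxon` x `char1..charN` of tip states (integers `1..k`).
#' @export
simulate_mk_characters <- function(tree, alpha, k, n_chars, seed = 1L) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  pre <- rev(seq_len(nrow(edge)))
  node_states <- with_local_seed(seed, {
    vapply(seq_len(n_chars), function(ch) {
      st <- integer(n_node)
      st[n_tip + 1L] <- sample.int(k, 1L)
      for (i in pre) {
        P <- mk1_transition(alpha, elen[i], k)
        st[edge[i, 2]] <- sample.int(k, 1L, prob = P[st[edge[i, 1]], ])
      }
      st
    }, integer(n_node))
  })
  tips <- as_tibble(node_states[seq_len(n_tip), , drop = FALSE],
                    .name_repair = ~ paste0("char", seq_len(n_chars)))
  tips <- mutate(tips, taxon = tree$tip.label, .before = 1)
  attr(tips, "node_states") <- node_states
  tips
}

#' Toy alignments with known haplotype and indel structure
#'
#' Builds a backbone of haplotypes by sequential point mutations (each step
#' mutates a previously untouched position, so pairwise distances along the
#' backbone are additive), replicates haplotypes to requested
#' multiplicities, and overlays gap spans with a known simple-indel-coding
#' answer. Ground truth (haplotype membership, expected multiplicities,
#' expected indel characters) is attached as attributes.
#'
#' @param n_haplotypes number of backbone haplotypes.
#' @param steps_between mutational steps between consecutive haplotypes
#'   (scalar or vector of length `n_haplotypes - 1`).
#' @param n_copies copies per haplotype (scalar or vector).
#' @param indel_spec optional list of `list(start, end, seqs)` gap spans;
#'   `seqs` are the sequence ids (e.g. `"H2_1"`) receiving the gap.
#' @param length alignment length.
#' @param seed integer seed.
#' @return named character vector of aligned sequences with attributes
#'   `haplotype_map` (id -> backbone index), `multiplicities`, and
#'   `sic_truth` (tibble of gap spans).
#' @export
make_toy_alignment <- function(n_haplotypes, steps_between = 1L,
                               n_copies = 1L, indel_spec = NULL,
                               length = 60L, seed = 1L) {
  steps <- rep_len(steps_between, max(0L, n_haplotypes - 1L))
  if (any(steps < 1)) abort("`steps_between` must be >= 1.")
  copies <- rep_len(n_copies, n_haplotypes)
  # mutations never fall inside indel spans, so gaps cannot hide the
  # substitutions separating haplotypes and the attached truth stays exact
  gap_pos <- unlist(lapply(indel_spec, function(g) g$start:g$end))
  mutable <- setdiff(seq_len(length), gap_pos)
  if (sum(steps) > base::length(mutable))
    abort("Alignment too short for the requested mutations.")
  with_local_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    free <- sample(mutable)             # unused positions, random order
    haps <- vector("list", n_haplotypes)
    haps[[1]] <- base
    used <- 0L
    for (i in seq_along(steps)) {
      h <- haps[[i]]
      for (s in seq_len(steps[i])) {
        used <- used + 1L
        pos <- free[used]
        h[pos] <- sample(setdiff(c("A", "C", "G", "T"), h[pos]), 1L)
      }
      haps[[i + 1L]] <- h
    }
    seqs <- character()
    map <- integer()
    for (i in seq_len(n_haplotypes)) {
      for (cp in seq_len(copies[i])) {
        id <- paste0("H", i, "_", cp)
        seqs[id] <- paste(haps[[i]], collapse = "")
        map[id] <- i
      }
    }
    for (g in indel_spec) {
      for (id in g$seqs) {
        v <- strsplit(seqs[id], "")[[1]]
        v[g$start:g$end] <- "-"
        seqs[id] <- paste(v, collapse = "")
      }
    }
    sic_truth <- if (length(indel_spec)) {
      bind_rows(lapply(indel_spec, function(g)
        tibble(start = g$start, end = g$end, n_bearers = length(g$seqs))))
    } else tibble(start = integer(), end = integer(), n_bearers = integer())
    structure(seqs, haplotype_map = map, multiplicities = copies,
              sic_truth = sic_truth)
  })
}

#' Simulate the default three-lineage study
#'
#' The default scenario mirrors the qualitative structure of a classic
#' integrative-delimitation setting: three lineages in one shared study
#' area, two of them ("lineage_OW" and "lineage_INV", the widespread
#' invader with the largest sample) with strongly overlapping niches, and
#' one ("lineage_NW") ecologically distinct; sample sizes 100/300/100.
#'
#' @param seed integer seed.
#' @param n_vars number of environmental layers.
#' @param grid_dims raster dimensions.
#' @return list with `rasters`, `occurrences` (all lineages, with years),
#'   and `specs` (the ground-truth niche parameters).
#' @export
simulate_study <- function(seed = 1L, n_vars = 6L, grid_dims = c(100, 100)) {
  rasters <- make_env_rasters(n_vars, grid_dims, smoothness = 5,
                              seed = seed,
                              correlations = list(c(1, 2, 0.5)))
  zero <- rep(0, n_vars - 2L)
  # the two overlapping niches share most of their environmental space but
  # are offset enough that equivalency is detectably violated ("similar but
  # not equivalent"), while the third niche is ecologically distinct
  specs <- list(
    lineage_OW  = lineage_spec("lineage_OW",  c(1.0, 0.3, zero), 0.10, 100L),
    lineage_INV = lineage_spec("lineage_INV", c(0.3, 1.0, zero), 0.10, 300L),
    lineage_NW  = lineage_spec("lineage_NW",  c(-1.0, -1.0, zero), 0.10, 100L)
  )
  occ <- purrr::imap_dfr(specs, function(sp, nm)
    sample_occurrences(sp, rasters, seed = seed + match(nm, names(specs))))
  list(rasters = rasters, occurrences = occ, specs = specs)
}
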