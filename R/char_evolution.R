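#' Mk1 transition probability matrix
#'
#' Under the one-parameter Markov k-state model all state changes share one
#' rate `alpha`, giving
#' `P_ii = 1/k + (k-1)/k * exp(-k*alpha*t)` and
#' `P_ij = 1/k - 1/k * exp(-k*alpha*t)` for `i != j`. Rows sum to 1; `t = 0`
#' yields the identity and `alpha*t -> Inf` the uniform stationary matrix.
#'
#' @param alpha substitution rate (>= 0).
#' @param t branch length (>= 0).
#' @param k number of states (>= 2).
#' @return a `k x k` probability matrix.
#' @export
mk1_transition <- function(alpha, t, k) {
  if (k < 2) abort("Mk needs at least 2 states.")
  if (alpha < 0 || t < 0) abort("`alpha` and `t` must be nonnegative.")
  ek <- exp(-k * alpha * t)
  off <- (1 - ek) / k
  m <- matrix(off, k, k)
  diag(m) <- 1 / k + (k - 1) / k * ek
  m
}

# Tip states -> likelihood matrix (tips x k). `states` is a named vector of
# integers in 1..k or NA (missing -> all-ones row).
tip_likelihoods <- function(tree, states, k) {
  n_tip <- length(tree$tip.label)
  L <- matrix(1, n_tip, k)
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips))
    abort(paste0("Tip(s) absent from the character matrix: ",
                 paste(missing_tips, collapse = ", ")))
  s <- states[tree$tip.label]
  obs <- !is.na(s)
  L[obs, ] <- 0
  L[cbind(which(obs), s[obs])] <- 1
  L
}

# Downward (pruning) pass. Returns per-node conditional likelihood vectors,
# log scaling factors, and the cached transition matrix per edge.
mk1_prune <- function(tree, states, alpha, k) {
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tree_po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, n_node, k)
  L[seq_len(n_tip), ] <- tip_likelihoods(tree, states, k)
  logscale <- numeric(n_node)
  P <- vector("list", nrow(tree_po$edge))
  for (i in seq_len(nrow(tree_po$edge))) {
    par <- tree_po$edge[i, 1]; child <- tree_po$edge[i, 2]
    P[[i]] <- mk1_transition(alpha, tree_po$edge.length[i], k)
    contrib <- as.vector(P[[i]] %*% L[child, ])
    L[par, ] <- L[par, ] * contrib
    logscale[par] <- logscale[par] + logscale[child]
    mx <- max(L[par, ])
    if (mx > 0 && (mx < 1e-150 || mx > 1e150)) {
      L[par, ] <- L[par, ] / mx
      logscale[par] <- logscale[par] + log(mx)
    }
  }
  root <- n_tip + 1L
  list(L = L, logscale = logscale, edge = tree_po$edge,
       edge.length = tree_po$edge.length, P = P, root = root, n_tip = n_tip)
}

#' Mk1 log-likelihood on a fixed rooted tree
#'
#' Felsenstein pruning with a uniform `1/k` root prior. Tips missing from
#' `states` are an error; tips whose state is `NA` contribute a vector of
#' ones (no information). Polytomies are treated as hard multifurcations.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param states named integer vector (names = tip labels, values in
#'   `1..k` or `NA`).
#' @param alpha substitution rate.
#' @param k number of states.
#' @return the log-likelihood (possibly `-Inf`).
#' @export
mk1_loglik <- function(tree, states, alpha, k) {
  pr <- mk1_prune(tree, states, alpha, k)
  lik <- sum(pr$L[pr$root, ] / k)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

#' Maximum-likelihood Mk1 rate
#'
#' One-dimensional bounded maximisation of [mk1_loglik()] over
#' `alpha` in `[1e-8, 1e3]`, searched on the log scale (tolerance 1e-8).
#' Invariant characters drive the optimum to the lower bound; this is
#' flagged in `rate_at_bound`.
#'
#' @inheritParams mk1_loglik
#' @param lower,upper search bounds for the rate.
#' @return list with `ml_rate`, `log_likelihood`, `rate_at_bound`.
#' @export
optimize_rate <- function(tree, states, k,
                          lower = 1e-8, upper = 1e3) {
  s <- states[tree$tip.label]
  if (sum(!is.na(s)) < 2L) abort("Need at least 2 non-missing tips.")
  f <- function(loga) mk1_loglik(tree, states, exp(loga), k)
  opt <- optimize(f, interval = log(c(lower, upper)), maximum = TRUE,
                  tol = 1e-8)
  rate <- exp(opt$maximum)
  at_bound <- rate <= lower * (1 + 1e-3) || rate >= upper * (1 - 1e-3)
  # optimize() never evaluates the interval endpoints; snap to the bound when
  # the surface is monotone up to it
  if (at_bound) {
    bnd <- if (rate <= lower * (1 + 1e-3)) lower else upper
    if (f(log(bnd)) >= opt$objective) {
      rate <- bnd
      opt$objective <- f(log(bnd))
    }
  }
  list(ml_rate = rate, log_likelihood = opt$objective,
       rate_at_bound = at_bound)
}

#' Marginal ancestral state reconstruction under Mk1
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state given the tip data, the rate and the uniform root prior, via
#' the rerooting formulation: the downward (pruning) partial likelihoods of
#' each node are combined with the complementary "rest-of-tree" partials
#' propagated from the root, and normalised. Equivalent to brute-force
#' summation over all internal-node state assignments.
#'
#' @inheritParams mk1_loglik
#' @param alpha substitution rate; if `NULL` (default) the ML rate from
#'   [optimize_rate()] is used.
#' @param state_labels optional state names for the probability columns.
#' @return an object of class `asr_fit`.
#' @export
marginal_asr <- function(tree, states, k, alpha = NULL, state_labels = NULL) {
  opt <- NULL
  if (is.null(alpha)) {
    opt <- optimize_rate(tree, states, k)
    alpha <- opt$ml_rate
  }
  pr <- mk1_prune(tree, states, alpha, k)
  n_tip <- pr$n_tip
  n_node <- nrow(pr$L)
  # children (with edge row index) per parent node
  kids <- split(seq_len(nrow(pr$edge)), pr$edge[, 1])
  U <- matrix(0, n_node, k)
  U[pr$root, ] <- 1 / k
  # preorder = reverse postorder on the edge list
  for (i in rev(seq_len(nrow(pr$edge)))) {
    par <- pr$edge[i, 1]; child <- pr$edge[i, 2]
    sib_edges <- setdiff(kids[[as.character(par)]], i)
    S <- U[par, ]
    for (j in sib_edges)
      S <- S * as.vector(pr$P[[j]] %*% pr$L[pr$edge[j, 2], ])
    u <- as.vector(t(pr$P[[i]]) %*% S)
    mx <- max(u)
    U[child, ] <- if (mx > 0) u / mx else u
  }
  probs <- pr$L * U
  probs <- probs / rowSums(probs)
  internal <- (n_tip + 1L):n_node
  anc <- as_tibble(probs[internal, , drop = FALSE],
                   .name_repair = ~ state_labels %||% paste0("state", seq_len(k)))
  anc <- mutate(anc, node = internal, .before = 1)
  ll <- mk1_loglik(tree, states, alpha, k)
  structure(
    list(tree = tree, k = k, ml_rate = alpha, log_likelihood = ll,
         rate_at_bound = opt$rate_at_bound %||% NA,
         anc = anc, probs = probs,
         state_labels = state_labels %||% paste0("state", seq_len(k))),
    class = "asr_fit"
  )
}

#' @export
print.asr_fit <- function(x, ...) {
  cat("<asr_fit> k = ", x$k, ", rate = ", signif(x$ml_rate, 5),
      ", logLik = ", signif(x$log_likelihood, 8), "\n", sep = "")
  print(x$anc, n = 5)
  invisible(x)
}

#' @export
tidy.asr_fit <- function(x, ...) {
  tidyr::pivot_longer(x$anc, -"node", names_to = "state",
                      values_to = "probability")
}

#' @export
glance.asr_fit <- function(x, ...) {
  tibble(k = x$k, ml_rate = x$ml_rate,
         log_likelihood = x$log_likelihood,
         rate_at_bound = x$rate_at_bound,
         n_tips = length(x$tree$tip.label))
}

#' Stacked-bar view of per-node ancestral state probabilities
#'
#' @param object an `asr_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.asr_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$node),
                                 y = .data$probability,
                                 fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "internal node", y = "marginal probability") +
    ggplot2::theme_minimal()
}

# Encode an observed character column as integers 1..k.
encode_states <- function(x, taxa, alphabet = NULL) {
  x <- as.character(x)
  obs <- sort(unique(x[!is.na(x)]))
  alphabet <- alphabet %||% obs
  unknown <- setdiff(obs, alphabet)
  if (length(unknown))
    abort(paste0("State(s) outside the declared alphabet: ",
                 paste(unknown, collapse = ", ")))
  setNames(match(x, alphabet), taxa)
}

#' Ancestral state reconstruction report across trees and characters
#'
#' Runs ML marginal ancestral state reconstruction for every combination of
#' input tree (e.g. the trees from two independent markers) and character
#' column. The hairpoint character uses its fixed three-state alphabet
#' (`absent`, `erect`, `reflexed`); meristic characters such as lamella
#' height use their observed states as an unordered Mk alphabet unless a
#' `state_map` recodes them (e.g. binning into `low`/`high`).
#'
#' @param trees named list of rooted `ape::phylo` trees. Trees without
#'   branch lengths get unit lengths, with a warning.
#' @param char_matrix data frame with a `taxon` column and one column per
#'   character; missing data as `NA`.
#' @param characters character columns to reconstruct (default: all but
#'   `taxon`).
#' @param alphabets optional named list giving a fixed state alphabet per
#'   character (default: observed states, sorted).
#' @param state_map optional named list of functions (or named vectors)
#'   recoding a character before reconstruction.
#' @return a tibble with one row per tree x character x internal node x
#'   state, plus columns `ml_rate`, `log_likelihood`; the fitted `asr_fit`
#'   objects are in attribute `fits`.
#' @export
asr_report <- function(trees, char_matrix, characters = NULL,
                       alphabets = list(hairpoint = c("absent", "erect", "reflexed")),
                       state_map = NULL) {
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  characters <- characters %||% setdiff(names(char_matrix), "taxon")
  fits <- list()
  rows <- list()
  for (tn in names(trees)) {
    tree <- trees[[tn]]
    if (is.null(tree$edge.length)) {
      warn(paste0("Tree '", tn, "' has no branch lengths; using 1.0."))
      tree$edge.length <- rep(1, nrow(tree$edge))
    }
    missing_tips <- setdiff(tree$tip.label, char_matrix$taxon)
    if (length(missing_tips))
      abort(paste0("Tip(s) of tree '", tn, "' absent from matrix: ",
                   paste(missing_tips, collapse = ", ")))
    for (ch in characters) {
      vals <- char_matrix[[ch]]
      map <- state_map[[ch]]
      if (!is.null(map))
        vals <- if (is.function(map)) map(vals) else unname(map[as.character(vals)])
      alpha_set <- alphabets[[ch]]
      st <- encode_states(vals, char_matrix$taxon, alpha_set)
      labels <- alpha_set %||% sort(unique(as.character(vals[!is.na(vals)])))
      kk <- length(labels)
      fit <- marginal_asr(tree, st, kk, state_labels = as.character(labels))
      fits[[paste(tn, ch, sep = ".")]] <- fit
      rows[[paste(tn, ch, sep = ".")]] <- tidy(fit) |>
        mutate(tree = tn, character = ch, ml_rate = fit$ml_rate,
               log_likelihood = fit$log_likelihood, .before = 1)
    }
  }
  structure(bind_rows(rows), fits = fits)
}

#' Write per-node ancestral state probabilities as CSV
#'
#' @param fit an `asr_fit`.
#' @param path output CSV path.
#' @export
write_asr_csv <- function(fit, path) {
  write.csv(fit$anc, path, row.names = FALSE)
  invisible(path)
}

#' Write a morphological character matrix as NEXUS
#'
#' Standard-datatype NEXUS export of a taxon x character table, missing data
#' as `?`.
#'
#' @param char_matrix data frame with a `taxon` column and character columns.
#' @param path output path.
#' @export
write_characters_nexus <- function(char_matrix, path) {
  chars <- setdiff(names(char_matrix), "taxon")
  codes <- vapply(chars, function(ch) {
    v <- as.character(char_matrix[[ch]])
    lv <- sort(unique(v[!is.na(v)]))
    out <- as.character(match(v, lv) - 1L)
    out[is.na(out)] <- "?"
    out
  }, character(nrow(char_matrix)))
  codes <- matrix(codes, nrow = nrow(char_matrix))
  lines <- c(
    "#NEXUS", "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", nrow(char_matrix),
           " NCHAR=", length(chars), ";"),
    "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"0123456789\";",
    "  MATRIX"
  )
  lines <- c(lines, paste0("    ", format(char_matrix$taxon), " ",
                           apply(codes, 1L, paste, collapse = "")),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
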