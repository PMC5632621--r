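test_that("Mk1 transition matrix: identity, stationary limit, closed form", {
  expect_equal(mk1_transition(0.7, 0, 3), diag(3))
  expect_equal(mk1_transition(50, 50, 4), matrix(1 / 4, 4, 4),
               tolerance = 1e-12)
  P <- mk1_transition(1, 1, 2)
  expect_equal(P[1, 1], 0.5 * (1 + exp(-2)))
  expect_equal(rowSums(mk1_transition(0.3, 0.9, 5)), rep(1, 5))
  expect_error(mk1_transition(1, 1, 1), "2 states")
})

test_that("pruning log-likelihood equals brute-force enumeration", {
  for (seed in 1:4) {
    fx <- random_tree_states(5, 3, seed)
    for (alpha in c(0.1, 0.7, 2)) {
      expect_equal(mk1_loglik(fx$tree, fx$states, alpha, 3),
                   brute_mk_loglik(fx$tree, fx$states, alpha, 3),
                   tolerance = 1e-9)
    }
  }
  # with missing tips
  fx <- random_tree_states(5, 3, 9)
  fx$states[2] <- NA
  expect_equal(mk1_loglik(fx$tree, fx$states, 0.5, 3),
               brute_mk_loglik(fx$tree, fx$states, 0.5, 3),
               tolerance = 1e-9)
})

test_that("degenerate data: impossible states, no data, absent tips", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  expect_identical(mk1_loglik(tr, c(a = 1L, b = 2L), 1, 2), -Inf)
  tr2 <- ape::read.tree(text = "(a:0.5,b:0.5);")
  expect_equal(mk1_loglik(tr2, c(a = NA_integer_, b = NA_integer_), 1, 2), 0)
  expect_error(mk1_loglik(tr2, c(a = 1L), 1, 2), "absent")
})

test_that("likelihood is invariant under rerooting (time reversibility)", {
  fx <- random_tree_states(6, 3, 17)
  ll <- mk1_loglik(fx$tree, fx$states, 0.6, 3)
  unrooted <- ape::unroot(fx$tree)
  for (node in c(1L, 3L, 5L)) {
    rr <- ape::root(unrooted, outgroup = node, resolve.root = TRUE)
    expect_equal(mk1_loglik(rr, fx$states, 0.6, 3), ll, tolerance = 1e-10)
  }
})

test_that("marginal reconstructions equal brute-force conditionals", {
  for (n_tip in c(4, 5, 6)) {
    for (k in c(2, 4)) {
      fx <- random_tree_states(n_tip, k, n_tip * 10 + k)
      fit <- marginal_asr(fx$tree, fx$states, k, alpha = 0.8)
      oracle <- brute_mk_marginals(fx$tree, fx$states, 0.8, k)
      got <- as.matrix(fit$anc[, -1])
      expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
      expect_equal(rowSums(got), rep(1, nrow(got)), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("symmetric two-tip case and near-certain reconstruction behave analytically", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  fit <- marginal_asr(tr, c(a = 1L, b = 2L), 2, alpha = 0.5)
  expect_equal(unlist(fit$anc[1, -1]), c(state1 = 0.5, state2 = 0.5))

  # all tips in one state on short branches: root near-certain
  tr5 <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  fit5 <- marginal_asr(tr5, setNames(rep(1L, 4), letters[1:4]), 3, alpha = 1)
  expect_gt(fit5$anc$state1[1], 0.99)
})

test_that("tip marginals on zero-length branches are the observed indicators", {
  tr <- ape::read.tree(text = "((a:0,b:0.5):0.3,c:0.4);")
  fit <- marginal_asr(tr, c(a = 1L, b = 2L, c = 2L), 2, alpha = 0.4)
  tip_probs <- fit$probs[1, ] / sum(fit$probs[1, ])   # tip "a", t = 0
  expect_equal(tip_probs, c(1, 0))
})

test_that("rate optimisation: boundary flag and grid-scan oracle", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  inv <- optimize_rate(tr, setNames(rep(1L, 4), letters[1:4]), 2)
  expect_true(inv$rate_at_bound)
  expect_equal(inv$ml_rate, 1e-8)

  fx <- random_tree_states(6, 2, 23)
  opt <- optimize_rate(fx$tree, fx$states, 2)
  grid <- exp(seq(log(1e-6), log(100), length.out = 2000))
  grid_best <- max(vapply(grid, function(a)
    mk1_loglik(fx$tree, fx$states, a, 2), numeric(1)))
  expect_gte(opt$log_likelihood + 1e-6, grid_best)
})

test_that("Mk1 log-likelihood matches an independent Mk implementation", {
  skip_if_not_installed("phytools")
  fx <- random_tree_states(6, 3, 29)
  x <- setNames(letters[fx$states], names(fx$states))
  rate <- 0.45
  Q <- matrix(rate, 3, 3); diag(Q) <- -2 * rate
  ext <- phytools::fitMk(fx$tree, x, fixedQ = Q, pi = "equal")
  expect_equal(mk1_loglik(fx$tree, fx$states, rate, 3),
               as.numeric(stats::logLik(ext)), tolerance = 1e-6)
})

test_that("asr_report reconstructs per tree and character, deterministically", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  cm <- data.frame(
    taxon = letters[1:4],
    hairpoint = c("erect", "erect", "reflexed", "absent"),
    lamella_height = c(5L, 6L, 1L, 2L)
  )
  rep1 <- asr_report(list(its1 = tr), cm)
  rep2 <- asr_report(list(its1 = tr), cm)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_setequal(unique(rep1$character), c("hairpoint", "lamella_height"))
  # internal nodes x states per character
  expect_equal(sum(rep1$character == "hairpoint"), 3L * 3L)
  expect_equal(sum(rep1$character == "lamella_height"), 3L * 4L)

  drop <- asr_report(list(its1 = tr), cm, characters = "hairpoint")
  expect_false("lamella_height" %in% drop$character)

  # a state mapping bins lamella height into a 2-state character
  binned <- asr_report(list(its1 = tr), cm, characters = "lamella_height",
                       state_map = list(lamella_height = function(v)
                         ifelse(v <= 2, "low", "high")))
  expect_equal(sum(binned$character == "lamella_height"), 3L * 2L)

  cm_bad <- cm[1:3, ]
  expect_error(asr_report(list(its1 = tr), cm_bad, characters = "hairpoint"),
               "absent")
})

test_that("clade-structured characters are recovered at internal nodes", {
  # two 5-tip clades with fixed, distinct states on a long-stem tree
  txt <- "((a1:0.1,a2:0.1,a3:0.1,a4:0.1,a5:0.1):2,(b1:0.1,b2:0.1,b3:0.1,b4:0.1,b5:0.1):2);"
  tr <- ape::read.tree(text = txt)
  st <- setNames(rep(c(1L, 2L), each = 5), tr$tip.label)
  fit <- marginal_asr(tr, st, 2)
  # the two clade ancestors should be confidently reconstructed
  anc <- fit$anc
  clade_nodes <- anc[anc$node != length(tr$tip.label) + 1L, ]
  states <- apply(as.matrix(clade_nodes[, -1]), 1L, which.max)
  conf <- apply(as.matrix(clade_nodes[, -1]), 1L, max)
  expect_equal(states, c(1L, 2L))
  expect_true(all(conf > 0.95))
})

test_that("tidy, glance and autoplot expose the fit", {
  fx <- random_tree_states(5, 3, 31)
  fit <- marginal_asr(fx$tree, fx$states, 3, alpha = 0.5,
                      state_labels = c("absent", "erect", "reflexed"))
  td <- tidy(fit)
  expect_setequal(unique(td$state), c("absent", "erect", "reflexed"))
  gl <- glance(fit)
  expect_equal(gl$k, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})
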