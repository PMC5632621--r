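test_that("SIC hand-worked cases: shared gap, subsumed gap, gap-free", {
  # gap-free alignment defines no characters
  clean <- c(s1 = "ACGTACGT", s2 = "ACGTACGA")
  expect_equal(nrow(simple_indel_coding(clean)$characters), 0L)

  # two sequences share gap (5,7); the third is ungapped
  shared <- c(s1 = "ACGT---TACGT", s2 = "ACGT---TACGT", s3 = "ACGTAAATACGT")
  sic <- simple_indel_coding(shared)
  expect_equal(sic$characters$start, 5L)
  expect_equal(sic$characters$end, 7L)
  expect_equal(unname(sic$scores[, 1]), c(1L, 1L, 0L))

  # gap (3,9) strictly contains gap (5,7): two characters, the contained one
  # inapplicable for the long-gap sequence
  sub <- c(s1 = "AC-------GTT", s2 = "ACGT---TACGT", s3 = "ACGTAAATACGT")
  sic2 <- simple_indel_coding(sub)
  expect_equal(nrow(sic2$characters), 2L)
  scores <- sic2$scores
  expect_equal(unname(scores[, "indel_3_9"]), c(1L, 0L, 0L))
  expect_equal(unname(scores[, "indel_5_7"]), c(NA_integer_, 1L, 0L))
})

test_that("terminal gaps define no characters and score missing where spanned", {
  aln <- c(s1 = "---TACGTACGT", s2 = "AC-TACGTACGT", s3 = "ACGTACGTACGT")
  sic <- simple_indel_coding(aln)
  expect_equal(nrow(sic$characters), 1L)     # only s2's internal (3,3) gap
  expect_equal(sic$characters$start, 3L)
  expect_true(is.na(sic$scores["s1", 1]))    # spanned by s1's terminal gap
  expect_equal(unname(sic$scores["s3", 1]), 0L)
})

test_that("SIC is invariant to sequence order", {
  aln <- c(s1 = "AC-------GTT", s2 = "ACGT---TACGT", s3 = "ACGTAAATACGT")
  a <- simple_indel_coding(aln)
  b <- simple_indel_coding(aln[c(3, 1, 2)])
  expect_equal(a$characters, b$characters)
  expect_equal(a$scores[names(aln), ], b$scores[names(aln), ])
})

test_that("haplotype collapsing: duplicates, missing-compatibility, all-distinct", {
  aln <- c(x1 = "ACGTACGT", x2 = "ACGTACGT", x3 = "ACGTACGT",
           x4 = "ACGAACGT", x5 = "ACCTACGT")
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h), 3L)
  expect_equal(sum(h$multiplicity), 5L)
  expect_equal(h$multiplicity[h$haplotype == "x1"], 3L)

  # a gap at the only differing position merges the pair
  merged <- collapse_haplotypes(c(a = "ACGTAC", b = "AC-TAC"))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$haplotype, "a")
  expect_equal(merged$sequence, "ACGTAC")    # missing filled from the member

  distinct <- collapse_haplotypes(c(a = "AAAA", b = "CCCC", c = "GGGG"))
  expect_equal(nrow(distinct), 3L)

  # gap-free input partitions exactly by string equality (direct oracle)
  set.seed(41)
  seqs <- setNames(sample(c("AAGG", "AAGC", "TTGG"), 12, replace = TRUE),
                   paste0("s", 1:12))
  h2 <- collapse_haplotypes(seqs)
  oracle <- table(unname(seqs))
  expect_equal(nrow(h2), length(oracle))
  expect_equal(sort(h2$multiplicity), sort(as.integer(oracle)))
})

test_that("ambiguous sequences merge with the most frequent compatible haplotype", {
  # "amb" is compatible with both AAAA (x2) and AAAC, which are mutually
  # incompatible; it must join the more frequent AAAA
  aln <- c(h1a = "AAAA", h1b = "AAAA", h2a = "AAAC", amb = "AAA-")
  expect_message(h <- collapse_haplotypes(aln), "mutually distinct")
  expect_equal(nrow(h), 2L)
  big <- h[h$multiplicity == 3L, ]
  expect_equal(nrow(big), 1L)
  expect_setequal(big$members[[1]], c("h1a", "h1b", "amb"))
  expect_equal(big$haplotype, "amb")   # lexicographically first member id
  expect_equal(big$sequence, "AAAA")   # missing position resolved
})

test_that("network construction: direct edge, one intermediate, hand-built toy", {
  h2 <- collapse_haplotypes(c(A = "AAAA", B = "AAAT"))
  n2 <- parsimony_network(h2, 10)
  expect_equal(igraph::vcount(n2$graph), 2L)
  expect_equal(igraph::ecount(n2$graph), 1L)

  h3 <- collapse_haplotypes(c(A = "AAAA", C = "AATT"))
  n3 <- parsimony_network(h3, 10)
  expect_equal(igraph::vcount(n3$graph), 3L)   # one hypothetical node
  v <- igraph::V(n3$graph)
  expect_equal(sum(v$hypothetical), 1L)
  deg <- igraph::degree(n3$graph)
  expect_equal(unname(deg[v$hypothetical]), 2L)

  # 4 haplotypes at backbone distances 1, 1, 2 (limit 3):
  # expected: A-B, B-C direct; C..D through 1 intermediate -> 5 nodes, 4 edges
  aln <- make_toy_alignment(4, steps_between = c(1, 1, 2),
                            n_copies = c(3, 1, 1, 1), seed = 5)
  h4 <- collapse_haplotypes(aln)
  n4 <- parsimony_network(h4, 3)
  expect_equal(igraph::vcount(n4$graph), 5L)
  expect_equal(igraph::ecount(n4$graph), 4L)
  expect_equal(igraph::components(n4$graph)$no, 1L)
  # minimal-intermediate check: total hypothetical nodes equal the
  # brute-force Steiner count for a path topology: sum over bridged pairs
  # of (d - 1) with intermediate reuse
  expect_equal(sum(igraph::V(n4$graph)$hypothetical), 1L)

  # multiplicity conservation
  expect_equal(sum(h4$multiplicity), length(aln))
})

test_that("pairs beyond the connection limit stay disconnected", {
  aln <- make_toy_alignment(2, steps_between = 5, seed = 6)
  h <- collapse_haplotypes(aln)
  n_lim <- parsimony_network(h, 4)
  expect_equal(igraph::components(n_lim$graph)$no, 2L)
  n_ok <- parsimony_network(h, 5)
  expect_equal(igraph::components(n_ok$graph)$no, 1L)
  expect_equal(sum(igraph::V(n_ok$graph)$hypothetical), 4L)
  expect_error(parsimony_network(h, 0), "connection_limit")
})

test_that("network edges always join nodes at unit distance", {
  for (seed in 1:5) {
    aln <- make_toy_alignment(4, steps_between = sample(1:3, 3, replace = TRUE),
                              n_copies = sample(1:3, 4, replace = TRUE),
                              seed = seed)
    h <- collapse_haplotypes(aln)
    net <- parsimony_network(h, 10)
    el <- igraph::as_edgelist(net$graph)
    v <- igraph::V(net$graph)
    seq_of <- setNames(v$sequence, v$name)
    d <- apply(el, 1L, function(e)
      nichedelim:::hap_distance(seq_of[e[1]], seq_of[e[2]]))
    expect_true(all(d == 1L))
    expect_equal(sum(h$multiplicity), length(aln))
  }
})

test_that("network edge set ignores haplotype input order", {
  aln <- make_toy_alignment(4, steps_between = c(1, 2, 1),
                            n_copies = c(2, 1, 1, 1), seed = 9)
  h <- collapse_haplotypes(aln)
  n1 <- parsimony_network(h, 10)
  n2 <- parsimony_network(h[rev(seq_len(nrow(h))), ], 10)
  canon <- function(n) {
    el <- igraph::as_edgelist(n$graph)
    el <- t(apply(el, 1L, sort))
    el[order(el[, 1], el[, 2]), ]
  }
  expect_equal(canon(n1), canon(n2))
})

test_that("per-group summary counts distinct and shared haplotypes", {
  aln <- c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAT", b1 = "AAAA", b2 = "CAAA")
  h <- collapse_haplotypes(aln)
  net <- parsimony_network(h, 10)
  groups <- c(a1 = "g1", a2 = "g1", a3 = "g1", b1 = "g2", b2 = "g2",
              zz = "g3")
  s <- network_summary(net, groups)
  expect_equal(s$counts$n_haplotypes[s$counts$group == "g1"], 2L)
  expect_equal(s$counts$n_haplotypes[s$counts$group == "g2"], 2L)
  expect_equal(s$counts$n_haplotypes[s$counts$group == "g3"], 0L)
  expect_equal(unique(s$sharing$haplotype), "a1")   # AAAA spans g1 and g2

  # all sequences identical: one haplotype in every group
  same <- collapse_haplotypes(c(a = "AAAA", b = "AAAA"))
  nets <- parsimony_network(same, 10)
  ss <- network_summary(nets, c(a = "g1", b = "g2"))
  expect_true(all(ss$counts$n_haplotypes == 1L))

  expect_error(network_summary(net, groups[1:3]), "Unlabeled")
})

test_that("alignment and network exports are readable", {
  aln <- c(s1 = "ACGT---TACGT", s2 = "ACGTAAATACGT", s3 = "ACGTAAATACGT")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "aln.fasta")
  write_alignment(aln, fa)
  back <- read_alignment(fa)
  expect_equal(back, aln)

  sic <- simple_indel_coding(aln)
  nx <- file.path(dir, "aln.nex")
  write_sic_nexus(aln, sic, nx)
  txt <- readLines(nx)
  expect_true(any(grepl("NCHAR=13", txt)))   # 12 positions + 1 indel char

  net <- parsimony_network(collapse_haplotypes(aln), 10)
  gml <- file.path(dir, "net.graphml")
  write_network(net, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
})
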