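#' Read an aligned FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of upper-case aligned sequences (equal
#'   lengths enforced).
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  check_alignment(seqs)
  seqs
}

check_alignment <- function(seqs) {
  if (length(seqs) < 1L) abort("Empty alignment.")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    abort("Sequences must carry unique ids.")
  if (length(unique(nchar(seqs))) != 1L)
    abort("All aligned sequences must have equal length.")
  invisible(seqs)
}

#' Write an alignment as FASTA
#' @param seqs named character vector of aligned sequences.
#' @param path output path.
#' @export
write_alignment <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

aln_matrix <- function(seqs) {
  check_alignment(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

# Gap runs per sequence: tibble(seq, start, end, terminal).
gap_runs <- function(m) {
  len <- ncol(m)
  out <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    if (length(gi))
      out[[rownames(m)[i]]] <- tibble(
        seq = rownames(m)[i], start = starts[gi], end = ends[gi],
        terminal = starts[gi] == 1L | ends[gi] == len
      )
  }
  if (length(out)) bind_rows(out) else
    tibble(seq = character(), start = integer(), end = integer(),
           terminal = logical())
}

#' Simple indel coding (SIC) of alignment gaps
#'
#' Every distinct *internal* gap span (identical start and end across
#' sequences; 1-based inclusive coordinates) becomes one binary character.
#' A sequence scores `1` (present) when it carries exactly that gap, `0`
#' (absent) when it has residues somewhere across the span, and `NA`
#' (inapplicable) when a strictly longer gap of that sequence contains the
#' span. Terminal gaps define no characters and score `NA` for every
#' character they span.
#'
#' @param alignment named character vector of aligned sequences (>= 2).
#' @return object of class `indel_characters`: list with `characters`
#'   (tibble `start`, `end`) and `scores` (sequences x characters matrix of
#'   1/0/`NA`).
#' @export
simple_indel_coding <- function(alignment) {
  if (length(alignment) < 2L) abort("Need at least 2 sequences.")
  m <- aln_matrix(alignment)
  runs <- gap_runs(m)
  chars <- runs |>
    filter(!.data$terminal) |>
    dplyr::distinct(.data$start, .data$end) |>
    arrange(.data$start, .data$end)
  scores <- matrix(NA_integer_, nrow(m), nrow(chars),
                   dimnames = list(rownames(m),
                                   if (nrow(chars)) paste0("indel_", chars$start, "_", chars$end)))
  for (j in seq_len(nrow(chars))) {
    s <- chars$start[j]; e <- chars$end[j]
    for (i in seq_len(nrow(m))) {
      id <- rownames(m)[i]
      my <- runs[runs$seq == id, , drop = FALSE]
      exact <- any(!my$terminal & my$start == s & my$end == e)
      term_over <- any(my$terminal & my$start <= e & my$end >= s)
      contains <- any(my$start <= s & my$end >= e & (my$end - my$start) > (e - s))
      scores[i, j] <- if (term_over || (!exact && contains)) NA_integer_
      else if (exact) 1L
      else 0L
    }
  }
  structure(list(characters = chars, scores = scores),
            class = "indel_characters")
}

#' @export
print.indel_characters <- function(x, ...) {
  cat("<indel_characters> ", nrow(x$characters), " indel character(s), ",
      nrow(x$scores), " sequence(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.indel_characters <- function(x, ...) {
  if (nrow(x$characters) == 0L)
    return(tibble(seq = character(), start = integer(), end = integer(),
                  score = integer()))
  tibble(
    seq = rep(rownames(x$scores), times = ncol(x$scores)),
    start = rep(x$characters$start, each = nrow(x$scores)),
    end = rep(x$characters$end, each = nrow(x$scores)),
    score = as.integer(x$scores)
  )
}

#' Write a SIC-augmented NEXUS matrix
#'
#' Writes the aligned sequences with the binary indel characters appended as
#' extra columns (the role SeqState plays in morphology-free pipelines):
#' DNA symbols plus `0`/`1`, missing as `?`.
#'
#' @param alignment named character vector of aligned sequences.
#' @param sic the [simple_indel_coding()] result for that alignment.
#' @param path output path.
#' @export
write_sic_nexus <- function(alignment, sic, path) {
  codes <- apply(sic$scores, 1L, function(r) {
    r2 <- as.character(r); r2[is.na(r2)] <- "?"
    paste(r2, collapse = "")
  })
  if (ncol(sic$scores) == 0L) codes <- rep("", length(alignment))
  total <- nchar(alignment[1]) + ncol(sic$scores)
  lines <- c(
    "#NEXUS", "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", length(alignment), " NCHAR=", total, ";"),
    "  FORMAT DATATYPE=STANDARD GAP=- MISSING=? SYMBOLS=\"ACGTN01\";",
    "  MATRIX",
    paste0("    ", format(names(alignment)), " ", alignment,
           codes[names(alignment)]),
    "  ;", "END;"
  )
  writeLines(lines, path)
  invisible(path)
}

missing_symbols <- c("-", "N", "?")

# Positions where both are observed must agree; gaps/N are wildcards.
compatible_seqs <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  obs <- !(va %in% missing_symbols) & !(vb %in% missing_symbols)
  all(va[obs] == vb[obs])
}

merge_seqs <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  take_b <- va %in% missing_symbols & !(vb %in% missing_symbols)
  va[take_b] <- vb[take_b]
  paste(va, collapse = "")
}

#' Collapse aligned sequences into haplotypes
#'
#' Gaps (and `N`/`?`) are treated as missing data. Sequences identical at
#' every position where both are observed are merged; merging is iterative
#' with a deterministic order (smallest-multiplicity haplotype merged into
#' its highest-multiplicity compatible partner; ties by id). When a
#' haplotype is compatible with two mutually incompatible haplotypes the
#' higher-multiplicity partner wins and the conflict is reported. The
#' representative id of a haplotype is the lexicographically first member
#' id.
#'
#' @param sequences named character vector of aligned sequences.
#' @return tibble with `haplotype` (representative id), `sequence`
#'   (missing positions filled in from members where known), `multiplicity`
#'   and list column `members`; multiplicities sum to the input count.
#' @export
collapse_haplotypes <- function(sequences) {
  check_alignment(sequences)
  # exact duplicates first
  groups <- split(names(sequences), unname(sequences))
  haps <- tibble(
    sequence = names(groups),
    members = unname(lapply(groups, sort)),
    multiplicity = unname(lengths(groups))
  ) |>
    mutate(haplotype = vapply(.data$members, `[`, character(1), 1L)) |>
    arrange(.data$haplotype)

  repeat {
    n_h <- nrow(haps)
    if (n_h < 2L) break
    comp <- matrix(FALSE, n_h, n_h)
    for (i in seq_len(n_h - 1L)) for (j in (i + 1L):n_h)
      comp[i, j] <- comp[j, i] <- compatible_seqs(haps$sequence[i],
                                                  haps$sequence[j])
    if (!any(comp)) break
    deg <- rowSums(comp)
    cand <- which(deg > 0)
    # the haplotype with the most missing data is the ambiguous one to
    # reassign; ties by multiplicity, then by id
    n_miss <- vapply(strsplit(haps$sequence[cand], ""), function(v)
      sum(v %in% missing_symbols), integer(1))
    ord <- order(-n_miss, haps$multiplicity[cand],
                 xtfrm(haps$haplotype[cand]))
    src <- cand[ord[1]]
    partners <- which(comp[src, ])
    if (length(partners) > 1L) {
      mutually <- all(comp[partners, partners][upper.tri(diag(length(partners)))])
      if (!mutually)
        inform(paste0("Haplotype ", haps$haplotype[src],
                      " compatible with mutually distinct haplotypes; ",
                      "merged with the most frequent one."))
    }
    dst <- partners[order(-haps$multiplicity[partners],
                          haps$haplotype[partners])][1]
    haps$sequence[dst] <- merge_seqs(haps$sequence[dst], haps$sequence[src])
    haps$members[[dst]] <- sort(c(haps$members[[dst]], haps$members[[src]]))
    haps$multiplicity[dst] <- haps$multiplicity[dst] + haps$multiplicity[src]
    haps$haplotype[dst] <- haps$members[[dst]][1]
    haps <- haps[-src, ]
  }
  haps |>
    select("haplotype", "sequence", "multiplicity", "members") |>
    arrange(.data$haplotype)
}

# Hamming distance ignoring positions missing in either sequence.
hap_distance <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  obs <- !(va %in% missing_symbols) & !(vb %in% missing_symbols)
  sum(va[obs] != vb[obs])
}

# Mutational path from a to b changing differing observed positions in
# left-to-right alignment order; returns the d-1 intermediate sequences.
intermediate_seqs <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  obs <- !(va %in% missing_symbols) & !(vb %in% missing_symbols)
  pos <- which(obs & va != vb)
  if (length(pos) < 2L) return(character())
  out <- character(length(pos) - 1L)
  cur <- va
  for (s in seq_len(length(pos) - 1L)) {
    cur[pos[s]] <- vb[pos[s]]
    out[s] <- paste(cur, collapse = "")
  }
  out
}

#' Statistical-parsimony haplotype network
#'
#' Connects haplotypes differing by single mutational steps, inserting
#' hypothetical intermediate haplotypes for pairs further apart. All pairs
#' at distance 1 are joined first; then, for increasing distance
#' `d = 2..connection_limit`, pairs still in different components are joined
#' through `d - 1` hypothetical nodes along a deterministic path (differing
#' positions mutated in left-to-right alignment order), reusing an existing
#' node whenever its sequence matches. Within a distance, pairs with higher
#' total multiplicity connect first (ties by ids). Pairs beyond the limit
#' stay in separate components.
#'
#' @param haplotypes tibble from [collapse_haplotypes()].
#' @param connection_limit maximum number of mutational steps bridged
#'   (default 10).
#' @return object of class `haplotype_network` wrapping an `igraph` graph
#'   whose vertices carry `name`, `multiplicity`, `hypothetical` and
#'   `sequence` attributes, plus the haplotype tibble.
#' @export
parsimony_network <- function(haplotypes, connection_limit = 10) {
  if (connection_limit < 1) abort("`connection_limit` must be >= 1.")
  if (nrow(haplotypes) < 1L) abort("Need at least one haplotype.")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(haplotypes),
                            name = haplotypes$haplotype,
                            multiplicity = haplotypes$multiplicity,
                            hypothetical = FALSE,
                            sequence = haplotypes$sequence)
  n <- nrow(haplotypes)
  if (n >= 2L) {
    dmat <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      dmat[i, j] <- dmat[j, i] <- hap_distance(haplotypes$sequence[i],
                                               haplotypes$sequence[j])
    add_edge <- function(g, u, v) {
      if (!igraph::are_adjacent(g, u, v)) g <- igraph::add_edges(g, c(u, v))
      g
    }
    # distance-1 pairs first
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (dmat[i, j] == 1L)
        g <- add_edge(g, haplotypes$haplotype[i], haplotypes$haplotype[j])
    hyp_count <- 0L
    for (d in 2:max(2L, connection_limit)) {
      if (d > connection_limit) break
      prs <- which(dmat == d & upper.tri(dmat), arr.ind = TRUE)
      if (nrow(prs) == 0L) next
      msum <- haplotypes$multiplicity[prs[, 1]] + haplotypes$multiplicity[prs[, 2]]
      ord <- order(-msum, haplotypes$haplotype[prs[, 1]],
                   haplotypes$haplotype[prs[, 2]])
      for (rix in ord) {
        i <- prs[rix, 1]; j <- prs[rix, 2]
        comp <- igraph::components(g)$membership
        if (comp[haplotypes$haplotype[i]] == comp[haplotypes$haplotype[j]])
          next
        mids <- intermediate_seqs(haplotypes$sequence[i],
                                  haplotypes$sequence[j])
        chain <- haplotypes$haplotype[i]
        for (sq in mids) {
          existing <- igraph::V(g)$name[igraph::V(g)$sequence == sq]
          if (length(existing)) {
            nd <- existing[1]
          } else {
            hyp_count <- hyp_count + 1L
            nd <- paste0("h", hyp_count)
            g <- igraph::add_vertices(g, 1L, name = nd, multiplicity = 0,
                                      hypothetical = TRUE, sequence = sq)
          }
          g <- add_edge(g, chain, nd)
          chain <- nd
        }
        g <- add_edge(g, chain, haplotypes$haplotype[j])
      }
    }
  }
  structure(list(graph = g, haplotypes = haplotypes,
                 connection_limit = connection_limit),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  v <- igraph::V(x$graph)
  cat("<haplotype_network> ", sum(!v$hypothetical), " observed + ",
      sum(v$hypothetical), " hypothetical haplotype(s), ",
      igraph::ecount(x$graph), " edge(s), ",
      igraph::components(x$graph)$no, " component(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.haplotype_network <- function(x, ...) {
  v <- igraph::V(x$graph)
  plot(x$graph,
       vertex.size = ifelse(v$hypothetical, 4, 8 + 4 * sqrt(v$multiplicity)),
       vertex.color = ifelse(v$hypothetical, "black", "grey80"),
       vertex.label = ifelse(v$hypothetical, NA, v$name), ...)
}

#' Export a haplotype network
#'
#' @param network a `haplotype_network`.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_network <- function(network, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- network$graph
  if (format == "dot") {
    # DOT has no boolean attribute type
    g <- igraph::set_vertex_attr(g, "hypothetical",
                                 value = as.integer(igraph::V(g)$hypothetical))
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Per-group haplotype counts and sharing table
#'
#' @param network a `haplotype_network`.
#' @param groups named character vector mapping member (sequence) ids to
#'   group labels (e.g. lineage assignments).
#' @return list of tibbles: `counts` (distinct observed haplotypes per
#'   group, 0 for empty groups) and `sharing` (haplotype x group member
#'   counts for haplotypes spanning more than one group).
#' @export
network_summary <- function(network, groups) {
  haps <- network$haplotypes
  members <- tidyr::unnest(select(haps, "haplotype", "members"),
                           "members")
  unlabeled <- setdiff(members$members, names(groups))
  if (length(unlabeled))
    abort(paste0("Unlabeled member(s): ", paste(unlabeled, collapse = ", ")))
  members$group <- unname(groups[members$members])
  counts <- members |>
    dplyr::distinct(.data$haplotype, .data$group) |>
    dplyr::count(.data$group, name = "n_haplotypes")
  empty <- setdiff(unique(unname(groups)), counts$group)
  if (length(empty))
    counts <- bind_rows(counts, tibble(group = empty, n_haplotypes = 0L))
  counts <- arrange(counts, .data$group)
  shared <- members |>
    dplyr::count(.data$haplotype, .data$group) |>
    group_by(.data$haplotype) |>
    filter(dplyr::n_distinct(.data$group) > 1L) |>
    ungroup()
  list(counts = counts, sharing = shared)
}
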