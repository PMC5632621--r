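#' Read and validate a run configuration
#'
#' Configurations are plain lists, optionally loaded from YAML. Unknown
#' fields are kept; referenced paths must exist; `reps >= 1` and
#' `0 < alpha < 1` are enforced.
#'
#' @param config a list or a path to a YAML file.
#' @return the validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  defaults <- list(min_year = 1990, grid_size = 100, reps = 100,
                   alpha = 0.05, seed = 1L, mode = "uncorrected",
                   thin_per_cell = TRUE, auto_screen = TRUE,
                   collinearity_threshold = 0.70, connection_limit = 10,
                   out_dir = ".")
  config <- utils::modifyList(defaults, config)
  for (fld in c("occurrences", "rasters", "alignment", "trees", "characters")) {
    for (p in unlist(config[[fld]]))
      if (is.character(p) && !file.exists(p))
        abort(paste0("Configured path does not exist (", fld, "): ", p))
  }
  if (config$reps < 1) abort("`reps` must be >= 1.")
  if (config$alpha <= 0 || config$alpha >= 1) abort("`alpha` must be in (0, 1).")
  config
}

write_run_log <- function(config, path, extra = list()) {
  log <- c(list(
    tool = "nichedelim",
    version = as.character(utils::packageVersion("nichedelim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(config),
    config = config
  ), extra)
  yaml::write_yaml(log, path)
  invisible(path)
}

#' Run the niche-comparison workflow
#'
#' Reads (or simulates) occurrences and rasters, applies the collection-year
#' filter, extracts environments, optionally collapses duplicates per cell
#' and screens variable collinearity, then runs [compare_all()] and writes
#' the comparison table, breadth table, PCA loadings/explained-variance
#' table, optional density plots, and a run log capturing every effective
#' parameter and seed.
#'
#' Config fields: `occurrences` (CSV path) *or* `simulate: {seed}`;
#' `rasters` (named list of `.asc` paths, unless simulating); `min_year`,
#' `thin_per_cell`, `auto_screen`, `collinearity_threshold`, `variables`,
#' `grid_size`, `mode`, `reps`, `alpha`, `seed`, `plots`, `out_dir`.
#'
#' @param config list or YAML path (see [read_run_config()]).
#' @return invisibly, a list with the `niche_comparison_set` and output
#'   paths.
#' @export
run_niche <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$simulate)) {
    sim_seed <- config$simulate$seed %||% config$seed
    sim <- simulate_study(seed = sim_seed)
    occ <- sim$occurrences
    rasters <- sim$rasters
  } else {
    if (is.null(config$occurrences) || is.null(config$rasters))
      abort("Config needs `occurrences` and `rasters` (or `simulate`).")
    occ <- read_occurrences(config$occurrences)
    rasters <- read_env_rasters(unlist(config$rasters),
                                names = names(config$rasters))
  }
  occ <- filter_by_year(occ, config$min_year)
  occ <- extract_env(occ, rasters)
  if (isTRUE(config$thin_per_cell)) occ <- thin_per_cell(occ, rasters)
  if (length(unique(occ$lineage)) < 2L)
    abort("Need at least 2 lineages after filtering.")
  bg <- env_background(rasters)
  vars <- config$variables %||% names(rasters$layers)
  if (isTRUE(config$auto_screen))
    vars <- as.character(screen_collinearity(bg[vars],
                                             config$collinearity_threshold))
  res <- compare_all(occ, bg[vars], R = config$grid_size, mode = config$mode,
                     reps = config$reps, alpha = config$alpha,
                     seed = config$seed)
  paths <- list(
    comparisons = file.path(config$out_dir, "niche_comparisons.csv"),
    breadth = file.path(config$out_dir, "niche_breadth.csv"),
    pca = file.path(config$out_dir, "pca_loadings.csv"),
    log = file.path(config$out_dir, "run_log.yaml")
  )
  write_comparison_csv(res, paths$comparisons,
                       dump_nulls = isTRUE(config$dump_nulls))
  write.csv(res$breadth, paths$breadth, row.names = FALSE)
  pca_tbl <- tidy(res$pca) |>
    left_join(glance(res$pca), by = "axis")
  write.csv(pca_tbl, paths$pca, row.names = FALSE)
  if (isTRUE(config$plots)) {
    for (l in names(res$grids)) {
      p <- autoplot(res$grids[[l]]) + ggplot2::ggtitle(l)
      ggplot2::ggsave(file.path(config$out_dir, paste0("niche_", l, ".png")),
                      p, width = 5, height = 4, dpi = 150)
    }
  }
  write_run_log(config, paths$log,
                extra = list(variables_used = vars,
                             n_records = nrow(occ),
                             lineages = sort(unique(occ$lineage))))
  invisible(list(result = res, paths = paths))
}

#' Run the character-evolution and haplotype workflow
#'
#' Reads an alignment, trees and a character matrix; writes the
#' SIC-augmented NEXUS and indel character CSV, the statistical-parsimony
#' haplotype network (GraphML + DOT) with its per-group summary, one
#' ancestral-state CSV per tree x character, and a run log.
#'
#' Config fields: `alignment` (FASTA), `trees` (named list of Newick
#' paths), `characters` (CSV with `taxon` column), `groups` (optional CSV
#' with `id,group` columns mapping sequence ids to lineages),
#' `connection_limit`, `state_map`, `out_dir`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with results and output paths.
#' @export
run_phylo <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  paths <- list(log = file.path(config$out_dir, "run_log.yaml"))

  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    sic <- simple_indel_coding(aln)
    paths$sic_nexus <- file.path(config$out_dir, "alignment_sic.nex")
    paths$sic_csv <- file.path(config$out_dir, "indel_characters.csv")
    write_sic_nexus(aln, sic, paths$sic_nexus)
    write.csv(tidy(sic), paths$sic_csv, row.names = FALSE)
    haps <- collapse_haplotypes(aln)
    net <- parsimony_network(haps, config$connection_limit)
    paths$graphml <- file.path(config$out_dir, "haplotype_network.graphml")
    paths$dot <- file.path(config$out_dir, "haplotype_network.dot")
    write_network(net, paths$graphml, "graphml")
    write_network(net, paths$dot, "dot")
    out$sic <- sic
    out$network <- net
    if (!is.null(config$groups)) {
      gdf <- read.csv(config$groups, stringsAsFactors = FALSE)
      groups <- setNames(gdf$group, gdf$id)
      summ <- network_summary(net, groups)
      paths$summary <- file.path(config$out_dir, "haplotype_summary.csv")
      write.csv(summ$counts, paths$summary, row.names = FALSE)
      out$summary <- summ
    }
  }

  if (!is.null(config$trees) && !is.null(config$characters)) {
    trees <- lapply(config$trees, ape::read.tree)
    cm <- read.csv(config$characters, stringsAsFactors = FALSE)
    rep_tbl <- asr_report(trees, cm, state_map = config$state_map)
    out$asr <- rep_tbl
    fits <- attr(rep_tbl, "fits")
    for (nm in names(fits)) {
      p <- file.path(config$out_dir, paste0("asr_", gsub("\\.", "_", nm), ".csv"))
      write_asr_csv(fits[[nm]], p)
      paths[[paste0("asr_", nm)]] <- p
    }
  }
  write_run_log(config, paths$log)
  invisible(list(result = out, paths = paths))
}
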