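#' Run the full discovery pipeline on files
#'
#' Wires the whole analysis end to end: read the network, abundance (or
#' BLAST hits plus gene-to-reaction mapping), and group files; compute
#' per-reaction statistics; discover significant subnetworks; write the
#' report files and a machine-readable run manifest
#' (`manifest.json`, recording every parameter, the seed and the package
#' version) into `out_dir`. A run with no significant subnetworks still
#' succeeds and writes a valid, header-only report.
#'
#' @param network_file Edge-list file (see [read_network()]).
#' @param abundance_file Abundance TSV; alternatively supply `hits` and
#'   `gene_map`.
#' @param groups_file Two-column sample/group TSV.
#' @param out_dir Output directory (created if needed).
#' @param hits,gene_map BLAST tabular input for [counts_from_hits()]
#'   (used when `abundance_file` is `NULL`).
#' @param g1,g2 Optional group labels (defaults: order of appearance).
#' @param mode,size_cap,seeds,chain_extend Search options; see
#'   [greedy_search()].
#' @param engine,b Inner test options; see [test_config()].
#' @param b_abund,b_struct,alpha_abund,alpha_struct Significance options;
#'   see [significance_config()].
#' @param normalize Analyze relative abundances?
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical report files.
#' @param dot Write DOT files per subnetwork?
#' @param quiet Suppress progress messages?
#' @return The `subnet_discovery` object, invisibly.
#' @export
run_pipeline <- function(network_file, abundance_file = NULL, groups_file,
                         out_dir, hits = NULL, gene_map = NULL,
                         g1 = NULL, g2 = NULL,
                         mode = "chain", engine = "permutation", b = 1000,
                         b_abund = 1000, b_struct = 1000,
                         alpha_abund = 0.05, alpha_struct = 0.05,
                         size_cap = 30, seeds = "all_edges",
                         chain_extend = "one", normalize = TRUE,
                         seed = 1, dot = TRUE, quiet = TRUE) {
  for (f in c(network_file, abundance_file, groups_file, hits, gene_map)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file not found: ", f, call. = FALSE)
    }
  }
  network <- read_network(network_file)
  abundance <- if (!is.null(abundance_file)) {
    read_abundance(abundance_file)
  } else {
    if (is.null(hits) || is.null(gene_map)) {
      stop("supply either abundance_file or hits + gene_map", call. = FALSE)
    }
    counts_from_hits(hits, gene_map)
  }
  groups <- read_groups(groups_file)
  design <- group_design(groups, g1 = g1, g2 = g2)

  config <- significance_config(
    b_abund = b_abund, b_struct = b_struct,
    alpha_abund = alpha_abund, alpha_struct = alpha_struct,
    test = test_config(engine = engine, b = b),
    seed = seed
  )
  discovery <- discover_subnetworks(
    network, abundance, design,
    config = config, mode = mode, size_cap = size_cap, seeds = seeds,
    chain_extend = chain_extend, normalize = normalize, quiet = quiet
  )

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(discovery, path = out_dir, dot = dot)
  manifest <- list(
    package = "diffsubnet",
    version = as.character(utils::packageVersion("diffsubnet")),
    network_file = network_file, abundance_file = abundance_file,
    groups_file = groups_file, hits = hits, gene_map = gene_map,
    g1 = design$g1, g2 = design$g2,
    mode = mode, engine = engine, b = b,
    b_abund = b_abund, b_struct = b_struct,
    alpha_abund = alpha_abund, alpha_struct = alpha_struct,
    size_cap = size_cap, seeds = seeds, chain_extend = chain_extend,
    normalize = normalize, seed = seed, dot = dot
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(discovery)
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()] and repeats the run
#' with the identical parameters and seed, reproducing its outputs.
#'
#' @param manifest_file Path to a manifest.
#' @param out_dir Output directory; defaults to the manifest's own
#'   directory.
#' @return The `subnet_discovery` object, invisibly.
#' @export
run_from_manifest <- function(manifest_file, out_dir = dirname(manifest_file)) {
  m <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  run_pipeline(
    network_file = m$network_file, abundance_file = m$abundance_file,
    groups_file = m$groups_file, out_dir = out_dir,
    hits = m$hits, gene_map = m$gene_map, g1 = m$g1, g2 = m$g2,
    mode = m$mode, engine = m$engine, b = m$b,
    b_abund = m$b_abund, b_struct = m$b_struct,
    alpha_abund = m$alpha_abund, alpha_struct = m$alpha_struct,
    size_cap = m$size_cap, seeds = m$seeds, chain_extend = m$chain_extend,
    normalize = m$normalize, seed = m$seed, dot = m$dot
  )
}

#' Write a simulated dataset to the standard file formats
#'
#' Emits the three standard inputs (`network.tsv`, `abundance.tsv`,
#' `groups.tsv`) plus the ground-truth planted chain (`planted.txt`) for a
#' simulated dataset, so the pipeline can be exercised end to end from
#' files.
#'
#' @param dataset A `simulated_dataset`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(out_dir, "network.tsv"),
    abundance = file.path(out_dir, "abundance.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    planted = file.path(out_dir, "planted.txt")
  )
  write_network(dataset$network, paths[["network"]])
  write_abundance(dataset$abundance, paths[["abundance"]])
  write_groups(dataset$groups, paths[["groups"]])
  writeLines(dataset$planted, paths[["planted"]])
  invisible(paths)
}
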