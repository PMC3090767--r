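#' Read a metabolic network from an edge-list file
#'
#' The canonical on-disk form of the global metabolic network is a plain-text
#' edge list: one reaction per line with four whitespace- or tab-separated
#' fields, `reaction_id source_compound target_compound reversible`, where
#' `reversible` is `0` (the reaction only runs source to target) or `1`
#' (either direction). Lines starting with `#` and blank lines are ignored.
#' Nodes are metabolic compounds; edges are reactions.
#'
#' @param path Path to the edge-list file.
#' @param dialect File dialect; only `"edge_tsv"` is implemented. Converters
#'   from other encodings (e.g. KGML) are out of scope and should emit this
#'   dialect instead.
#' @return A tibble with columns `reaction_id`, `source`, `target`,
#'   `reversible` (logical), one row per reaction, in file order.
#' @export
read_network <- function(path, dialect = "edge_tsv") {
  dialect <- match.arg(dialect, "edge_tsv")
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    return(tibble::tibble(
      reaction_id = character(), source = character(),
      target = character(), reversible = logical()
    ))
  }
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  nfield <- lengths(parts)
  if (any(nfield != 4L)) {
    bad <- keep[which(nfield != 4L)[1L]]
    stop("malformed network line ", bad, ": expected 4 fields (",
      "reaction_id, source, target, reversible), got ",
      nfield[which(nfield != 4L)[1L]],
      call. = FALSE
    )
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  rev_raw <- m[, 4L]
  if (!all(rev_raw %in% c("0", "1"))) {
    bad <- keep[which(!rev_raw %in% c("0", "1"))[1L]]
    stop("malformed network line ", bad,
      ": reversibility flag must be 0 or 1",
      call. = FALSE
    )
  }
  ids <- m[, 1L]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    where <- keep[which(ids == dup)]
    stop("duplicate reaction id '", dup, "' (lines ",
      paste(where, collapse = ", "), ")",
      call. = FALSE
    )
  }
  tibble::tibble(
    reaction_id = ids, source = m[, 2L], target = m[, 3L],
    reversible = rev_raw == "1"
  )
}

#' Write a metabolic network to an edge-list file
#'
#' Inverse of [read_network()]: writing then reading reproduces the network
#' exactly, including edge order.
#'
#' @param network Network tibble (see [read_network()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  network <- validate_network(network)
  writeLines(
    c(
      "# reaction_id\tsource\ttarget\treversible",
      sprintf(
        "%s\t%s\t%s\t%d", network$reaction_id, network$source,
        network$target, as.integer(network$reversible)
      )
    ),
    path
  )
  invisible(path)
}

#' Validate a metabolic network tibble
#'
#' Checks the network invariants: required columns, unique reaction ids, no
#' missing fields. Self-loops and parallel edges (distinct reaction ids
#' between the same compound pair) are allowed; the graph may be
#' disconnected.
#'
#' @param network A data frame with columns `reaction_id`, `source`,
#'   `target`, `reversible`.
#' @return The validated network as a tibble (invisibly usable in pipes).
#' @export
validate_network <- function(network) {
  req <- c("reaction_id", "source", "target", "reversible")
  missing_cols <- setdiff(req, names(network))
  if (length(missing_cols) > 0L) {
    stop("network is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(network$reaction_id)) {
    dup <- network$reaction_id[duplicated(network$reaction_id)][1L]
    stop("duplicate reaction id '", dup, "' in network", call. = FALSE)
  }
  if (anyNA(network[req])) {
    stop("network contains missing values", call. = FALSE)
  }
  tibble::as_tibble(network[req])
}

#' Read a reaction-by-sample abundance matrix
#'
#' Expects a TSV whose header row names the samples, whose first column holds
#' reaction identifiers, and whose remaining cells are non-negative numbers
#' (mapped-read counts, possibly fractional).
#'
#' @param path Path to the abundance TSV.
#' @return A tibble with a `reaction_id` column followed by one numeric
#'   column per sample, rows and columns in file order.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) {
    stop("abundance file not found: ", path, call. = FALSE)
  }
  hdr <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t", fixed = TRUE)[[1L]]
  samples <- hdr[-1L]
  if (anyDuplicated(samples)) {
    dup <- samples[duplicated(samples)][1L]
    stop("duplicated sample column '", dup, "' in ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, colClasses = "character"
  )
  if (ncol(df) < 2L) {
    stop("abundance file needs a reaction column plus at least one sample",
      call. = FALSE
    )
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated reaction id '", ids[duplicated(ids)][1L], "' in ", path,
      call. = FALSE
    )
  }
  vals <- lapply(seq_along(samples), function(j) {
    x <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(x) & !is.na(df[[j + 1L]]))
    if (length(bad) > 0L || anyNA(df[[j + 1L]])) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(df[[j + 1L]]))[1L]
      stop("non-numeric abundance for reaction '", ids[row],
        "', sample '", samples[j], "'",
        call. = FALSE
      )
    }
    neg <- which(x < 0)
    if (length(neg) > 0L) {
      stop("negative abundance for reaction '", ids[neg[1L]],
        "', sample '", samples[j], "'",
        call. = FALSE
      )
    }
    x
  })
  names(vals) <- samples
  tibble::as_tibble(c(list(reaction_id = ids), vals))
}

#' Write an abundance matrix to TSV
#'
#' @param abundance Abundance tibble (see [read_abundance()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  stopifnot(names(abundance)[1L] == "reaction_id")
  readr::write_tsv(abundance, path)
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' A two-column TSV (`sample_id`, `group`) assigning every sample to one of
#' exactly two phenotypic groups. A header row is detected and skipped if its
#' first field is literally `sample_id`.
#'
#' @param path Path to the group TSV.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) {
    stop("groups file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    header = FALSE, stringsAsFactors = FALSE,
    comment.char = "#"
  )
  if (ncol(df) != 2L) {
    stop("groups file must have two columns (sample_id, group)", call. = FALSE)
  }
  if (identical(df[1L, 1L], "sample_id")) df <- df[-1L, , drop = FALSE]
  tibble::tibble(sample_id = as.character(df[[1L]]), group = as.character(df[[2L]]))
}

#' @rdname read_groups
#' @param groups Groups tibble.
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(groups[c("sample_id", "group")], path)
  invisible(path)
}

#' Normalize a two-group sample design
#'
#' Takes a `sample_id`/`group` table and fixes which label plays the role of
#' the first group (G1, the group in which positive Z-scores indicate
#' enrichment). Every sample must be assigned, there must be exactly two
#' distinct labels, and each group needs at least two samples.
#'
#' @param groups A data frame with columns `sample_id` and `group`, or an
#'   existing `group_design`.
#' @param g1,g2 Optional group labels; default to the first and second label
#'   in order of appearance.
#' @return A `group_design` object (list with `sample_id`, `group`, `g1`,
#'   `g2`).
#' @export
group_design <- function(groups, g1 = NULL, g2 = NULL) {
  if (inherits(groups, "group_design")) {
    return(groups)
  }
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  sample_id <- as.character(groups$sample_id)
  group <- as.character(groups$group)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample id '", sample_id[duplicated(sample_id)][1L], "'",
      call. = FALSE
    )
  }
  labs <- unique(group)
  if (length(labs) != 2L) {
    stop("exactly two group labels required, found ", length(labs),
      call. = FALSE
    )
  }
  g1 <- g1 %||% labs[1L]
  g2 <- g2 %||% setdiff(labs, g1)
  if (!all(c(g1, g2) %in% labs) || g1 == g2) {
    stop("g1/g2 must name the two distinct group labels", call. = FALSE)
  }
  if (min(table(group)) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, group = group, g1 = g1, g2 = g2),
    class = "group_design"
  )
}

#' @export
print.group_design <- function(x, ...) {
  cat(
    "<group_design> ", sum(x$group == x$g1), " x '", x$g1, "'  vs  ",
    sum(x$group == x$g2), " x '", x$g2, "'\n",
    sep = ""
  )
  invisible(x)
}

#' Build reaction counts from BLAST tabular hits
#'
#' Consumes standard 12-column BLAST tabular output (`query, subject,
#' %identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore`) together with a gene-to-reaction mapping and
#' produces a reaction-by-sample abundance matrix. For each query the best
#' hit is taken (highest bitscore; ties broken by lowest e-value, then first
#' occurrence in the file). Queries whose best hit fails the filters
#' (`evalue < max_evalue`, `bitscore > min_bitscore`,
#' `%identity > min_identity`; defaults match common practice for mapping gut
#' metagenome reads against KEGG genes) are dropped. A gene mapping to
#' several reactions contributes to each of them: a full count per reaction
#' by default, or `1/m` with `multi = "fractional"`.
#'
#' Best hits whose subject gene has no entry in the mapping are not an
#' error; they are tallied in the `"unmapped"` attribute of the result.
#'
#' @param hits Either a named character vector of per-sample BLAST tabular
#'   files (names are sample ids; unnamed entries use the file base name), or
#'   a single file with 13 columns whose first column is the sample id.
#' @param gene_map Path to a two-column headerless TSV mapping subject gene
#'   ids to reaction ids (one row per pair; one-to-many allowed).
#' @param max_evalue,min_bitscore,min_identity Best-hit filter thresholds.
#' @param multi How multi-mapping genes are counted: `"once"` adds a full
#'   count to every mapped reaction, `"fractional"` splits the count evenly.
#' @return Abundance tibble as from [read_abundance()], reactions sorted by
#'   id, one column per sample in input order. Attributes: `unmapped` (tibble
#'   of unmapped subject genes and their query counts) and `n_dropped`
#'   (queries whose best hit failed the filters).
#' @export
counts_from_hits <- function(hits, gene_map, max_evalue = 1e-5,
                             min_bitscore = 50, min_identity = 50,
                             multi = c("once", "fractional")) {
  multi <- match.arg(multi)
  blast_cols <- c(
    "query", "subject", "identity", "length", "mismatches", "gapopens",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  read_one <- function(f) {
    if (!file.exists(f)) stop("hits file not found: ", f, call. = FALSE)
    utils::read.delim(f,
      header = FALSE, stringsAsFactors = FALSE,
      comment.char = "#"
    )
  }
  if (length(hits) > 1L || !is.null(names(hits))) {
    snames <- names(hits) %||% rep("", length(hits))
    blank <- !nzchar(snames)
    snames[blank] <- sub("\\.[^.]*$", "", basename(unname(hits[blank])))
    tabs <- purrr::map2(unname(hits), snames, function(f, s) {
      tab <- read_one(f)
      if (ncol(tab) != 12L) {
        stop("expected 12 BLAST tabular columns in ", f, ", got ", ncol(tab),
          call. = FALSE
        )
      }
      names(tab) <- blast_cols
      dplyr::mutate(tab, sample = s, .before = 1L)
    })
    tab <- dplyr::bind_rows(tabs)
  } else {
    tab <- read_one(hits)
    if (ncol(tab) == 13L) {
      names(tab) <- c("sample", blast_cols)
    } else if (ncol(tab) == 12L) {
      names(tab) <- blast_cols
      tab$sample <- sub("\\.[^.]*$", "", basename(hits))
    } else {
      stop("expected 12 or 13 columns in ", hits, ", got ", ncol(tab),
        call. = FALSE
      )
    }
  }
  sample_order <- unique(tab$sample)

  best <- tab |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(
      .data$sample, .data$query, dplyr::desc(.data$bitscore),
      .data$evalue, .data$.row
    ) |>
    dplyr::distinct(.data$sample, .data$query, .keep_all = TRUE)
  pass <- best |>
    dplyr::filter(
      .data$evalue < max_evalue,
      .data$bitscore > min_bitscore,
      .data$identity > min_identity
    )
  n_dropped <- nrow(best) - nrow(pass)

  map <- utils::read.delim(gene_map,
    header = FALSE, stringsAsFactors = FALSE,
    comment.char = "#"
  )
  if (ncol(map) < 2L) {
    stop("gene map must have two columns (gene_id, reaction_id)", call. = FALSE)
  }
  map <- tibble::tibble(
    subject = as.character(map[[1L]]),
    reaction_id = as.character(map[[2L]])
  ) |> dplyr::distinct()
  map <- dplyr::mutate(map,
    weight = if (multi == "once") 1 else 1 / dplyr::n(),
    .by = "subject"
  )

  unmapped <- pass |>
    dplyr::anti_join(map, by = "subject") |>
    dplyr::count(.data$subject, name = "n_queries")

  counts <- pass |>
    dplyr::inner_join(map, by = "subject", relationship = "many-to-many") |>
    dplyr::summarise(
      count = sum(.data$weight),
      .by = c("reaction_id", "sample")
    ) |>
    tidyr::pivot_wider(
      names_from = "sample", values_from = "count", values_fill = 0
    ) |>
    dplyr::arrange(.data$reaction_id)
  for (s in setdiff(sample_order, names(counts))) counts[[s]] <- 0
  counts <- counts[c("reaction_id", sample_order)]
  attr(counts, "unmapped") <- unmapped
  attr(counts, "n_dropped") <- n_dropped
  counts
}

#' Write the discovery report
#'
#' Renders discovery output as plain-text tables: `subnetworks.tsv` (one row
#' per reported subnetwork: rank, both p-values, size, score, enriched
#' group, comma-separated member reactions), `reactions.tsv` (per-reaction
#' group means, p-value, Z-score, and the rank of the subnetwork containing
#' the reaction, if any), and optionally one Graphviz DOT file per
#' subnetwork. Subnetworks are ranked by `p_abund` (ties by `p_struct`, then
#' larger absolute score).
#'
#' @param results A `subnet_discovery` object from [discover_subnetworks()],
#'   or a tibble shaped like `tidy()` of one.
#' @param stats Per-reaction statistics tibble (taken from `results` when it
#'   is a discovery object).
#' @param path Output directory; created if needed.
#' @param network Network tibble, required for DOT output when `results` is
#'   a plain tibble.
#' @param dot Write one DOT file per subnetwork?
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(results, stats = NULL, path, network = NULL,
                         dot = TRUE) {
  if (inherits(results, "subnet_discovery")) {
    stats <- stats %||% results$stats
    network <- network %||% results$network
    results <- tidy(results)
  }
  if (is.null(stats)) stop("per-reaction stats are required", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  if (nrow(results) > 0L) {
    if (anyNA(results$p_abund) || anyNA(results$p_struct) ||
      any(is.nan(results$p_abund)) || any(is.nan(results$p_struct))) {
      stop("cannot rank results: missing or NaN p-values", call. = FALSE)
    }
    results <- results |>
      dplyr::arrange(
        .data$p_abund, .data$p_struct, dplyr::desc(abs(.data$score))
      ) |>
      dplyr::mutate(rank = dplyr::row_number())
  } else {
    results$rank <- integer()
  }

  sub_tab <- results |>
    dplyr::mutate(
      reactions = purrr::map_chr(.data$reactions, paste, collapse = ",")
    ) |>
    dplyr::select(
      "rank", "p_abund", "p_struct", "k", "score", "enriched_in", "reactions"
    )
  f <- file.path(path, "subnetworks.tsv")
  readr::write_tsv(sub_tab, f)
  written <- c(written, f)

  member_rank <- results |>
    dplyr::select("rank", "reactions") |>
    tidyr::unnest_longer("reactions", values_to = "reaction_id") |>
    dplyr::distinct(.data$reaction_id, .keep_all = TRUE) |>
    dplyr::mutate(reaction_id = as.character(.data$reaction_id))
  rx_tab <- stats |>
    dplyr::left_join(member_rank, by = "reaction_id") |>
    dplyr::rename(subnetwork_rank = "rank")
  f <- file.path(path, "reactions.tsv")
  readr::write_tsv(rx_tab, f)
  written <- c(written, f)

  if (isTRUE(dot) && nrow(results) > 0L) {
    if (is.null(network)) {
      stop("network required for DOT output", call. = FALSE)
    }
    for (i in seq_len(nrow(results))) {
      f <- file.path(path, sprintf("subnetwork_%02d.dot", results$rank[i]))
      write_subnetwork_dot(network, results$reactions[[i]], f)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Export a subnetwork as a Graphviz DOT file
#'
#' @param network Network tibble.
#' @param reactions Character vector of member reaction ids.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subnetwork_dot <- function(network, reactions, path) {
  edges <- network[match(reactions, network$reaction_id), , drop = FALSE]
  if (anyNA(edges$reaction_id)) {
    stop("reaction(s) not present in network: ",
      paste(setdiff(reactions, network$reaction_id), collapse = ", "),
      call. = FALSE
    )
  }
  attrs <- ifelse(
    edges$reversible,
    sprintf("[label=\"%s\", dir=both]", edges$reaction_id),
    sprintf("[label=\"%s\"]", edges$reaction_id)
  )
  writeLines(
    c(
      "digraph subnetwork {",
      sprintf("  \"%s\" -> \"%s\" %s;", edges$source, edges$target, attrs),
      "}"
    ),
    path
  )
  invisible(path)
}
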