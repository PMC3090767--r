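#' Edge adjacency of a metabolic network
#'
#' Two reactions (edges) are adjacent when they share at least one compound
#' endpoint — the line-graph view under which subnetwork connectivity is
#' defined. The relation is symmetric and excludes the edge itself.
#'
#' @param network Network tibble.
#' @return A named list: for every reaction id, the character vector of
#'   adjacent reaction ids.
#' @export
edge_adjacency <- function(network) {
  network <- validate_network(network)
  ids <- network$reaction_id
  by_comp <- split(
    rep(ids, 2L),
    c(network$source, network$target)
  )
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (grp in by_comp) {
    grp <- unique(grp)
    if (length(grp) < 2L) next
    for (e in grp) adj[[e]] <- c(adj[[e]], setdiff(grp, e))
  }
  lapply(adj, function(x) sort(unique(x %||% character())))
}

new_subnetwork <- function(edges, score, mode) {
  structure(
    list(
      edges = as.character(edges), k = length(edges),
      score = if (length(edges) == 0L) -Inf else score, mode = mode
    ),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  if (x$k == 0L) {
    cat("<subnetwork> empty (", x$mode, " mode)\n", sep = "")
  } else {
    cat(
      "<subnetwork> k = ", x$k, ", score = ", format(x$score, digits = 4),
      " (", x$mode, " mode)\n  ", paste(x$edges, collapse = " "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.subnetwork <- function(x, ...) {
  tibble::tibble(
    reaction_id = x$edges,
    position = seq_along(x$edges)
  )
}

# Shared preprocessing for the compiled search: integer-coded endpoints and
# C-locale lexicographic ranks for deterministic tie-breaking.
greedy_prep <- function(network) {
  comps <- unique(c(network$source, network$target))
  list(
    ids = network$reaction_id,
    src = match(network$source, comps) - 1L,
    tgt = match(network$target, comps) - 1L,
    rev = network$reversible,
    lexr = match(
      network$reaction_id,
      sort(network$reaction_id, method = "radix")
    ),
    n_comp = length(comps)
  )
}

# weights argument (named vector, possibly partial) -> per-edge vector
weight_vector <- function(weights, ids) {
  if (is.null(names(weights)) && length(weights) == length(ids)) {
    w <- as.numeric(weights)
  } else {
    w <- as.numeric(weights[ids])
    w[is.na(w)] <- 0
  }
  if (any(!is.finite(w))) {
    stop("edge weights must be finite", call. = FALSE)
  }
  w
}

greedy_run <- function(prep, w, mode, k_fixed, size_cap, seed_idx, both_ends) {
  res <- greedy_core(
    prep$src, prep$tgt, prep$rev, w, prep$lexr, prep$n_comp,
    if (mode == "subgraph") 0L else 1L,
    if (is.null(k_fixed)) -1L else as.integer(k_fixed),
    as.integer(size_cap), seed_idx - 1L, both_ends
  )
  res
}

#' Greedy maximum-weight subnetwork search
#'
#' A subnetwork of `k` edges with weights `w_1..w_k` has aggregate score
#' `sum(w) / sqrt(k)`. The `sqrt(k)` scaling (the classical normalization
#' for a sum of `k` standard-normal scores) is what keeps free-size search
#' parsimonious: an extension is only worth keeping when its weight exceeds
#' roughly the running mean times `sqrt(k) * (sqrt(1 + 1/k) - 1)`, so a
#' strong core is not diluted by mediocre positive edges, whereas an
#' unnormalized sum grows monotonically under any positive extension.
#'
#' From every seed edge, repeatedly adds the highest-weight frontier edge —
#' any edge adjacent to the current set in `"subgraph"` mode, or any
#' direction-compatible extension at either end of the current simple path
#' in `"chain"` mode — recording the aggregate score after every addition,
#' until the frontier is empty or `size_cap` edges are reached. With
#' `k_fixed` absent the candidate from a seed is its best-scoring prefix
#' (free size); with `k_fixed` given it is the prefix of exactly `k_fixed`
#' edges (seeds that cannot grow that far contribute nothing). The returned
#' subnetwork is the best candidate over all seeds; all ties are broken
#' deterministically (higher score, then fewer edges, then lexicographically
#' smallest sorted reaction-id list; weight ties during growth prefer the
#' lexicographically smaller reaction id), so repeated runs are
#' reproducible.
#'
#' Reversible reactions may be traversed in either direction in chain mode;
#' an irreversible reaction can only be appended leaving its source and
#' entering its target. Self-loop reactions may appear in subgraph-mode
#' results but never in chains.
#'
#' @param network Network tibble.
#' @param weights Named numeric vector of edge weights (reaction id ->
#'   signed Z-score); reactions without a weight get 0. An unnamed vector of
#'   `nrow(network)` weights in edge order is also accepted.
#' @param mode `"subgraph"` (any connected edge set) or `"chain"` (simple
#'   direction-compatible path).
#' @param k_fixed Optional fixed subnetwork size.
#' @param size_cap Hard cap on growth (guards against pathological growth on
#'   dense graphs).
#' @param seeds Grow from `"all_edges"` or only `"positive_edges"`.
#' @param chain_extend Extend chains at only `"one"` end (forward from the
#'   seed's exit compound; the default, matching the classical rule that
#'   each added reaction follows the previously added one) or at `"both"`
#'   ends of the current path.
#' @return A `subnetwork` object: `edges` (reaction ids in addition order),
#'   `k`, `score` (aggregate, i.e. weight sum over `sqrt(k)`), `mode`. An
#'   explicit empty subnetwork (`k = 0`) when no candidate exists.
#' @export
greedy_search <- function(network, weights, mode = c("subgraph", "chain"),
                          k_fixed = NULL, size_cap = 30,
                          seeds = c("all_edges", "positive_edges"),
                          chain_extend = c("one", "both")) {
  mode <- match.arg(mode)
  seeds <- match.arg(seeds)
  chain_extend <- match.arg(chain_extend)
  network <- validate_network(network)
  stopifnot(size_cap >= 1)
  if (!is.null(k_fixed)) {
    stopifnot(k_fixed >= 1)
    if (k_fixed > size_cap) {
      stop("k_fixed must not exceed size_cap", call. = FALSE)
    }
  }
  if (nrow(network) == 0L) {
    return(new_subnetwork(character(), -Inf, mode))
  }
  prep <- greedy_prep(network)
  w <- weight_vector(weights, prep$ids)
  seed_idx <- if (seeds == "all_edges") seq_along(w) else which(w > 0)
  if (length(seed_idx) == 0L) {
    return(new_subnetwork(character(), -Inf, mode))
  }
  res <- greedy_run(
    prep, w, mode, k_fixed, size_cap, seed_idx,
    chain_extend == "both"
  )
  new_subnetwork(prep$ids[res$edges], res$score, mode)
}

#' Exact maximum-weight subnetwork by exhaustive enumeration
#'
#' Test oracle for the (NP-hard) maximum-weight connected-subgraph problem:
#' enumerates every connected edge subset of size `k` (subgraph mode) or
#' every simple direction-compatible path of `k` edges (chain mode) and
#' returns the optimum, with the same deterministic tie-breaking as
#' [greedy_search()]. Guarded to at most 16 edges.
#'
#' @inheritParams greedy_search
#' @param k Exact subnetwork size.
#' @return A `subnetwork` object, empty when no feasible subset of size `k`
#'   exists.
#' @export
brute_force_search <- function(network, weights, k,
                               mode = c("subgraph", "chain")) {
  mode <- match.arg(mode)
  network <- validate_network(network)
  stopifnot(k >= 1)
  if (nrow(network) > 16L) {
    stop("brute_force_search is limited to networks with <= 16 edges",
      call. = FALSE
    )
  }
  if (nrow(network) == 0L || k > nrow(network)) {
    return(new_subnetwork(character(), -Inf, mode))
  }
  ids <- network$reaction_id
  w <- weight_vector(weights, ids)
  lexr <- match(ids, sort(ids, method = "radix"))

  best <- NULL
  consider <- function(edge_idx) {
    cand <- list(
      score = sum(w[edge_idx]) / sqrt(length(edge_idx)), k = length(edge_idx),
      lex = sort(lexr[edge_idx]), edges = edge_idx
    )
    if (is.null(best) ||
      cand$score > best$score ||
      (cand$score == best$score &&
        identical(cand$k, best$k) &&
        paste(cand$lex, collapse = ",") < paste(best$lex, collapse = ",")
      )) {
      best <<- cand
    }
  }

  if (mode == "subgraph") {
    adj <- edge_adjacency(network)
    adj_idx <- lapply(adj, function(a) match(a, ids))
    connected <- function(sub) {
      seen <- sub[1L]
      queue <- sub[1L]
      while (length(queue) > 0L) {
        e <- queue[1L]
        queue <- queue[-1L]
        nb <- intersect(adj_idx[[e]], sub)
        new <- setdiff(nb, seen)
        seen <- c(seen, new)
        queue <- c(queue, new)
      }
      length(seen) == length(sub)
    }
    subsets <- utils::combn(length(ids), k, simplify = FALSE)
    for (sub in subsets) if (connected(sub)) consider(sub)
  } else {
    src <- network$source
    tgt <- network$target
    rv <- network$reversible
    inc <- split(
      rep(seq_along(ids), 2L),
      c(src, tgt)
    )
    inc <- lapply(inc, unique)
    extend <- function(path, end, used_comp) {
      if (length(path) == k) {
        consider(path)
        return(invisible())
      }
      for (f in inc[[end]] %||% integer()) {
        if (f %in% path || src[f] == tgt[f]) next
        ok <- src[f] == end || (rv[f] && tgt[f] == end)
        if (!ok) next
        other <- if (src[f] == end) tgt[f] else src[f]
        if (other %in% used_comp) next
        extend(c(path, f), other, c(used_comp, other))
      }
    }
    for (s in seq_along(ids)) {
      if (src[s] == tgt[s]) next
      extend(s, tgt[s], c(src[s], tgt[s]))
      if (rv[s]) extend(s, src[s], c(src[s], tgt[s]))
    }
  }
  if (is.null(best)) {
    return(new_subnetwork(character(), -Inf, mode))
  }
  new_subnetwork(ids[best$edges], best$score, mode)
}

#' Check subnetwork validity
#'
#' `is_connected_edge_set()` checks that a set of reactions forms a
#' connected subgraph under edge adjacency. `is_valid_chain()` checks that
#' the set can be ordered into a simple direction-compatible path of
#' compounds (reversible edges may be traversed either way; self-loops are
#' never valid chain members).
#'
#' @param network Network tibble.
#' @param reactions Character vector of member reaction ids.
#' @return Logical scalar.
#' @export
is_connected_edge_set <- function(network, reactions) {
  if (length(reactions) == 0L) {
    return(FALSE)
  }
  sub <- network[network$reaction_id %in% reactions, , drop = FALSE]
  if (nrow(sub) != length(unique(reactions))) {
    return(FALSE)
  }
  adj <- edge_adjacency(sub)
  seen <- sub$reaction_id[1L]
  queue <- seen
  while (length(queue) > 0L) {
    e <- queue[1L]
    queue <- queue[-1L]
    new <- setdiff(adj[[e]], seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == nrow(sub)
}

#' @rdname is_connected_edge_set
#' @export
is_valid_chain <- function(network, reactions) {
  k <- length(reactions)
  if (k == 0L) {
    return(FALSE)
  }
  sub <- network[match(reactions, network$reaction_id), , drop = FALSE]
  if (anyNA(sub$reaction_id) || any(sub$source == sub$target)) {
    return(FALSE)
  }
  src <- sub$source
  tgt <- sub$target
  rv <- sub$reversible
  found <- FALSE
  extend <- function(used, end, comps) {
    if (found) {
      return(invisible())
    }
    if (length(used) == k) {
      found <<- TRUE
      return(invisible())
    }
    for (f in setdiff(seq_len(k), used)) {
      ok_fwd <- src[f] == end
      ok_bwd <- rv[f] && tgt[f] == end
      if (ok_fwd && !(tgt[f] %in% comps)) {
        extend(c(used, f), tgt[f], c(comps, tgt[f]))
      }
      if (ok_bwd && !(src[f] %in% comps)) {
        extend(c(used, f), src[f], c(comps, src[f]))
      }
    }
  }
  for (s in seq_len(k)) {
    extend(s, tgt[s], c(src[s], tgt[s]))
    if (rv[s]) extend(s, src[s], c(src[s], tgt[s]))
    if (found) {
      return(TRUE)
    }
  }
  found
}
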