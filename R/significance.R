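#' Configuration of subnetwork significance testing and discovery
#'
#' Bundles the permutation budgets and significance thresholds for the two
#' subnetwork p-values together with the per-reaction [test_config()] used
#' when sample labels are permuted. Defaults follow the standard protocol:
#' 1000 permutations for each null and a 0.05 threshold on both p-values.
#'
#' @param b_abund Label permutations for `p_abund`.
#' @param b_struct Weight permutations for `p_struct`.
#' @param alpha_abund,alpha_struct Significance thresholds; a subnetwork is
#'   reported when `p_abund <= alpha_abund` and `p_struct <= alpha_struct`.
#' @param test Inner [test_config()] used to recompute per-reaction
#'   p-values under label permutation. Observed and permuted scores are
#'   always computed with the same engine, preserving exchangeability; the
#'   `"tdist"` engine is the fast option when nested permutation is too
#'   expensive.
#' @param seed Optional integer seed making all permutation draws (and
#'   therefore both p-values and discovery output) reproducible.
#' @return A `significance_config` list.
#' @export
significance_config <- function(b_abund = 1000, b_struct = 1000,
                                alpha_abund = 0.05, alpha_struct = 0.05,
                                test = test_config(), seed = NULL) {
  stopifnot(
    b_abund >= 1, b_struct >= 1,
    alpha_abund > 0, alpha_abund < 1, alpha_struct > 0, alpha_struct < 1
  )
  structure(
    list(
      b_abund = as.integer(b_abund), b_struct = as.integer(b_struct),
      alpha_abund = alpha_abund, alpha_struct = alpha_struct,
      test = test, seed = seed
    ),
    class = "significance_config"
  )
}

#' Abundance-permutation p-value of a subnetwork
#'
#' Tests whether the subnetwork's aggregate score (sum of member signed
#' Z-scores over `sqrt(k)`; the scaling is constant for a fixed member set,
#' so plain sums are compared) could arise without any group difference, by
#' permuting the
#' sample-to-group assignment, recomputing the member reactions' p-values
#' and Z-scores under each permuted labelling with the same engine as the
#' observed statistics, and comparing permuted scores to the observed one:
#' `p_abund = (r + 1) / (B + 1)` with `r` the number of permutations whose
#' score is at least the observed score. The null is one-sided in the
#' search direction; subnetworks enriched in group 2 are assessed with
#' `direction = -1`. This p-value ignores network topology entirely.
#'
#' @param subnetwork A `subnetwork` object (or list with an `edges` field).
#' @param abundance Abundance tibble; every member reaction must have a row
#'   (all-zero rows are acceptable).
#' @param groups Groups tibble or [group_design()].
#' @param config A [significance_config()].
#' @param direction `+1` for subnetworks found on the original weights
#'   (enrichment in group 1), `-1` for the mirrored search.
#' @param normalize Use per-sample relative abundances (must match how the
#'   observed statistics were computed).
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
p_abund <- function(subnetwork, abundance, groups,
                    config = significance_config(), direction = 1,
                    normalize = TRUE, seed = config$seed) {
  edges <- subnetwork$edges
  stopifnot(length(edges) >= 1L, direction %in% c(-1, 1))
  missing_rows <- setdiff(edges, abundance$reaction_id)
  if (length(missing_rows) > 0L) {
    stop("subnetwork member(s) missing from abundance matrix: ",
      paste(missing_rows, collapse = ", "),
      call. = FALSE
    )
  }
  design <- group_design(groups)
  X <- abundance_matrix(abundance)
  if (normalize) {
    tot <- colSums(X)
    if (any(tot <= 0)) {
      stop("sample '", colnames(X)[which(tot <= 0)[1L]],
        "' has zero total abundance",
        call. = FALSE
      )
    }
    X <- sweep(X, 2L, tot, "/")
  }
  lab <- design$group[match(colnames(X), design$sample_id)]
  memb <- as.numeric(lab == design$g1)
  Xm <- X[edges, , drop = FALSE]
  with_seed_if(seed, p_abund_impl(Xm, memb, config, direction))
}

# Scores under permuted labels. With the exhaustive permutation engine the
# inner p-value for ANY labelling is a rank within the same enumerated
# t-table, so the full null costs one pass over the C(n, n1) assignments.
p_abund_impl <- function(Xm, memb, config, direction) {
  tcfg <- config$test
  n <- length(memb)
  n1 <- sum(memb)
  B <- config$b_abund
  use_exhaustive <- tcfg$engine == "permutation" && tcfg$exhaustive &&
    choose(n, n1) <= tcfg$exhaustive_cap

  score_from <- function(t, p, floor_p) {
    p <- pmin(pmax(p, floor_p), 1)
    z <- sign(t) * qnorm(1 - p / 2)
    direction * colSums(z)
  }

  if (use_exhaustive) {
    A <- all_assignments(n, n1)
    M <- ncol(A)
    wt <- welch_t_matrix(Xm, A)
    absT <- abs(wt$t)
    # p at every assignment: fraction of assignments at least as extreme
    P <- t(apply(absT, 1L, function(v) {
      (length(v) - rank(v, ties.method = "min") + 1) / length(v)
    }))
    if (nrow(Xm) == 1L) P <- matrix(P, nrow = 1L)
    scores <- score_from(wt$t, P, 1 / M)
    j0 <- observed_column(A, memb)
    obs <- scores[j0]
    idx <- sample.int(M, B, replace = TRUE)
    r <- sum(scores[idx] >= obs)
    return((r + 1) / (B + 1))
  }

  if (tcfg$engine == "tdist") {
    A <- cbind(memb, random_assignments(n, n1, B))
    wt <- welch_t_matrix(Xm, A)
    p <- 2 * pt(abs(wt$t), wt$df, lower.tail = FALSE)
    scores <- score_from(wt$t, p, 1 / (tcfg$b + 1))
    obs <- scores[1L]
    r <- sum(scores[-1L] >= obs)
    return((r + 1) / (B + 1))
  }

  # Monte-Carlo inner permutations, nested: O(B_abund * b * k)
  inner <- function(mb) {
    Ain <- cbind(mb, random_assignments(n, sum(mb), tcfg$b))
    wt <- welch_t_matrix(Xm, Ain)
    tobs <- abs(wt$t[, 1L])
    r <- rowSums(abs(wt$t[, -1L, drop = FALSE]) >= tobs)
    p <- (r + 1) / (tcfg$b + 1)
    z <- sign(wt$t[, 1L]) * qnorm(1 - p / 2)
    direction * sum(z)
  }
  obs <- inner(memb)
  nulls <- vapply(seq_len(B), function(i) {
    inner(sample(memb))
  }, numeric(1))
  (sum(nulls >= obs) + 1) / (B + 1)
}

#' Structure-aware p-value of a subnetwork
#'
#' Measures how easily the network topology alone produces a subnetwork as
#' good as the observed one: the edge weights are permuted uniformly across
#' all edges of the (current) global network, the greedy search is re-run,
#' and the resulting maximal aggregate scores form the null distribution.
#' `p_struct = (r + 1) / (B + 1)` with `r` the number of null searches
#' scoring at least the observed score. This guards against the selection
#' bias of dense topologies, where a handful of random high-weight edges
#' always assemble into a high-scoring subnetwork.
#'
#' With `null = "free"` (the default) each null search is the same
#' free-size search that produced the observed subnetwork, so observed and
#' null statistics are exchangeable under weight permutation and the
#' p-value is exactly calibrated. `null = "fixed_k"` re-runs the null
#' searches in fixed-size mode with `k` matched to the observed subnetwork
#' (the classical protocol for fixed-length searches); when the observed
#' search was free-size this ignores the optimization over subnetwork size
#' and is measurably anti-conservative. Fixed-size null searches that
#' cannot produce a size-`k` subnetwork (disconnected remnants) contribute
#' `-Inf` and can never count as extreme.
#'
#' @param subnetwork The observed `subnetwork` (produced by
#'   [greedy_search()] on `network` with `weights`).
#' @param network Network tibble (the network the search ran on, i.e. after
#'   any removals from earlier discovery iterations).
#' @param weights The edge weights used by that search (already negated for
#'   a mirrored search).
#' @param config A [significance_config()].
#' @param mode,size_cap,seeds,chain_extend Search options; must match the
#'   observed search.
#' @param null Null search protocol: `"free"` (re-run the free-size search,
#'   exactly exchangeable with a free-size observed search) or `"fixed_k"`
#'   (size-matched null searches).
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
p_struct <- function(subnetwork, network, weights,
                     config = significance_config(),
                     mode = subnetwork$mode, size_cap = 30,
                     seeds = c("all_edges", "positive_edges"),
                     chain_extend = c("one", "both"),
                     null = c("free", "fixed_k"), seed = config$seed) {
  seeds <- match.arg(seeds)
  chain_extend <- match.arg(chain_extend)
  null <- match.arg(null)
  k <- subnetwork$k
  stopifnot(k >= 1)
  if (k > size_cap) {
    stop("subnetwork size exceeds size_cap", call. = FALSE)
  }
  network <- validate_network(network)
  prep <- greedy_prep(network)
  w <- weight_vector(weights, prep$ids)
  obs <- sum(w[match(subnetwork$edges, prep$ids)]) / sqrt(k)
  B <- config$b_struct
  both <- chain_extend == "both"
  k_null <- if (null == "fixed_k") k else NULL
  with_seed_if(seed, {
    r <- 0L
    for (b in seq_len(B)) {
      wp <- w[sample.int(length(w))]
      seed_idx <- if (seeds == "all_edges") seq_along(wp) else which(wp > 0)
      if (length(seed_idx) == 0L) next # null search infeasible: -Inf
      res <- greedy_run(prep, wp, mode, k_null, size_cap, seed_idx, both)
      if (length(res$edges) > 0L && res$score >= obs) r <- r + 1L
    }
    (r + 1) / (B + 1)
  })
}

#' Discover all significant differentially abundant subnetworks
#'
#' The full discovery loop: per-reaction statistics are computed once, the
#' free-size greedy search proposes the best subnetwork on the remaining
#' network, and the candidate is accepted when both `p_abund` and
#' `p_struct` fall at or below their thresholds. Accepted subnetworks have
#' their edges removed from the network and the search repeats. When the
#' search on the original weights yields no significant candidate, the
#' mirrored search on negated weights is evaluated (finding subnetworks
#' enriched in group 2); the loop stops when neither direction produces a
#' significant subnetwork. Termination is guaranteed because every accepted
#' subnetwork removes at least one edge.
#'
#' Network edges without an abundance row are given an all-zero row (they
#' can never score positive); abundance rows absent from the network are
#' kept for per-reaction statistics but excluded from the search.
#'
#' @param network Network tibble.
#' @param abundance Abundance tibble.
#' @param groups Groups tibble or [group_design()].
#' @param config A [significance_config()] (holds the permutation budgets,
#'   thresholds, inner test engine and seed).
#' @param mode Search mode; reaction chains are the default as successively
#'   connected reactions are the biologically interesting structure.
#' @param size_cap,seeds,chain_extend Passed to [greedy_search()].
#' @param normalize Analyze per-sample relative abundances?
#' @param max_results Safety cap on the number of reported subnetworks.
#' @param quiet Suppress per-iteration progress messages?
#' @return A `subnet_discovery` object; see [tidy.subnet_discovery()] for
#'   the tabular view. Contains `results` (list of accepted subnetworks
#'   with their p-values), `stats` (per-reaction tibble), `network`,
#'   `config` and the search options.
#' @export
discover_subnetworks <- function(network, abundance, groups,
                                 config = significance_config(),
                                 mode = c("chain", "subgraph"),
                                 size_cap = 30,
                                 seeds = c("all_edges", "positive_edges"),
                                 chain_extend = c("one", "both"),
                                 normalize = TRUE, max_results = 50,
                                 quiet = TRUE) {
  mode <- match.arg(mode)
  seeds <- match.arg(seeds)
  chain_extend <- match.arg(chain_extend)
  network <- validate_network(network)
  design <- group_design(groups)

  # reconcile network and abundance: zero rows for unmeasured edges
  missing_edges <- setdiff(network$reaction_id, abundance$reaction_id)
  if (length(missing_edges) > 0L) {
    zeros <- tibble::as_tibble(c(
      list(reaction_id = missing_edges),
      stats::setNames(
        rep(list(rep(0, length(missing_edges))), ncol(abundance) - 1L),
        names(abundance)[-1L]
      )
    ))
    abundance <- dplyr::bind_rows(abundance, zeros)
  }

  stats <- compute_reaction_stats(abundance, design, config$test,
    normalize = normalize
  )
  wfull <- stats::setNames(stats$z, stats$reaction_id)

  X <- abundance_matrix(abundance)
  if (normalize) X <- sweep(X, 2L, colSums(X), "/")
  lab <- design$group[match(colnames(X), design$sample_id)]
  memb <- as.numeric(lab == design$g1)

  inner_cfg <- config
  inner_cfg$seed <- NULL

  run <- function() {
    net <- network
    results <- list()
    repeat {
      accepted <- FALSE
      for (dir in c(1, -1)) {
        if (nrow(net) == 0L) break
        w <- dir * wfull[net$reaction_id]
        s <- greedy_search(net, w,
          mode = mode, size_cap = size_cap,
          seeds = seeds, chain_extend = chain_extend
        )
        if (s$k == 0L) next
        pa <- with_seed_if(
          NULL,
          p_abund_impl(
            X[s$edges, , drop = FALSE], memb, inner_cfg, dir
          )
        )
        ps <- p_struct(s, net, w, inner_cfg,
          mode = mode, size_cap = size_cap,
          seeds = seeds, chain_extend = chain_extend, seed = NULL
        )
        if (!quiet) {
          message(sprintf(
            "iteration %d (%s): k=%d score=%.3f p_abund=%.4g p_struct=%.4g [%d edges left]",
            length(results) + 1L, if (dir == 1) design$g1 else design$g2,
            s$k, s$score, pa, ps, nrow(net)
          ))
        }
        if (pa <= config$alpha_abund && ps <= config$alpha_struct) {
          results[[length(results) + 1L]] <- list(
            subnetwork = s,
            p_abund = pa, p_struct = ps,
            score = sum(wfull[s$edges]) / sqrt(s$k),
            enriched_in = if (dir == 1) design$g1 else design$g2
          )
          net <- net[!net$reaction_id %in% s$edges, , drop = FALSE]
          accepted <- TRUE
          break
        }
      }
      if (!accepted || length(results) >= max_results || nrow(net) == 0L) {
        break
      }
    }
    results
  }
  results <- with_seed_if(config$seed, run())

  structure(
    list(
      results = results, stats = stats, network = network, design = design,
      config = config, mode = mode, size_cap = size_cap, seeds = seeds,
      chain_extend = chain_extend, normalize = normalize
    ),
    class = "subnet_discovery"
  )
}

#' @export
print.subnet_discovery <- function(x, ...) {
  cat(
    "<subnet_discovery> ", length(x$results), " significant subnetwork(s), ",
    nrow(x$stats), " reactions tested (", x$mode, " mode)\n",
    sep = ""
  )
  if (length(x$results) > 0L) print(tidy(x))
  invisible(x)
}
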