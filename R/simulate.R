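#' Parameters of the planted-signal simulation
#'
#' Describes the simulated two-group study used for calibration and
#' benchmarking: per-reaction abundances are Gaussian with a fixed relative
#' standard deviation, and a chain of consecutive reactions is planted as
#' enriched in group 1 by shifting its means to a chosen two-sample
#' significance boundary. Defaults match the standard design: five subjects
#' per group, relative standard deviation 0.2, a planted chain of length 5
#' (10 is the other standard choice), effect placed at the 0.01 boundary
#' (0.05 is the weaker alternative), 500 reactions with baseline means
#' drawn log-uniformly from 10 to 1000.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param rsd Relative standard deviation (sd / mean) of every reaction's
#'   abundance distribution.
#' @param planted_length Length of the planted enriched chain (0 for a null
#'   dataset).
#' @param effect_alpha Two-sided significance level at which the planted
#'   mean shift places the expected two-sample t statistic (see
#'   [effect_shift()]).
#' @param n_reactions Total number of reactions (network edges).
#' @param n_compounds Number of compounds (network nodes); must allow a
#'   connected graph (`n_reactions >= n_compounds - 1`).
#' @param baseline_means Either a length-2 range for log-uniform sampling
#'   of per-reaction baseline means, or an explicit vector of means
#'   (recycled by sampling with replacement) such as an empirical list from
#'   a real study.
#' @param p_reversible Probability that a simulated reaction is reversible.
#' @param seed Optional integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 5, rsd = 0.2, planted_length = 5,
                              effect_alpha = 0.01, n_reactions = 500,
                              n_compounds = 400, baseline_means = c(10, 1000),
                              p_reversible = 0.5, seed = NULL) {
  stopifnot(
    n_per_group >= 2, rsd > 0, planted_length >= 0,
    planted_length <= n_reactions, effect_alpha > 0, effect_alpha < 1,
    n_reactions >= 1, n_compounds >= 2
  )
  structure(
    list(
      n_per_group = as.integer(n_per_group), rsd = rsd,
      planted_length = as.integer(planted_length),
      effect_alpha = effect_alpha, n_reactions = as.integer(n_reactions),
      n_compounds = as.integer(n_compounds),
      baseline_means = baseline_means, p_reversible = p_reversible,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Simulate a connected metabolic network with an embedded chain
#'
#' Builds a random connected compound graph of `n_reactions` edges
#' containing a designated simple path of `embed_path_length` reactions
#' (the site of the planted signal): the path comes first, remaining
#' compounds are attached by random tree edges, and any leftover reactions
#' become random extra edges (parallel edges allowed, self-loops avoided).
#' Edge orientations are random; each reaction is reversible with
#' probability `p_reversible`. The designated path is oriented head-to-tail
#' so it is always a valid chain.
#'
#' @param n_compounds,n_reactions Graph size; requires
#'   `n_compounds >= embed_path_length + 1` and
#'   `n_reactions >= max(embed_path_length, n_compounds - 1)`.
#' @param embed_path_length Length (in edges) of the designated path; 0 for
#'   none.
#' @param p_reversible Reversibility probability.
#' @param seed Optional seed.
#' @return A list with `network` (tibble) and `planted` (reaction ids of
#'   the designated path, possibly empty).
#' @export
simulate_network <- function(n_compounds, n_reactions, embed_path_length = 0,
                             p_reversible = 0.5, seed = NULL) {
  L <- as.integer(embed_path_length)
  if (n_reactions < L) {
    stop("n_reactions must be at least embed_path_length", call. = FALSE)
  }
  if (n_compounds < L + 1L) {
    stop("n_compounds must be at least embed_path_length + 1", call. = FALSE)
  }
  if (n_reactions < n_compounds - 1L) {
    stop("n_reactions must be at least n_compounds - 1 for a connected graph",
      call. = FALSE
    )
  }
  with_seed_if(seed, {
    comp <- sprintf("C%04d", seq_len(n_compounds))
    rid <- sprintf("R%04d", seq_len(n_reactions))
    src <- character(n_reactions)
    tgt <- character(n_reactions)
    e <- 0L
    # designated path C1 -> C2 -> ... -> C(L+1)
    if (L > 0L) {
      src[seq_len(L)] <- comp[seq_len(L)]
      tgt[seq_len(L)] <- comp[seq_len(L) + 1L]
      e <- L
    }
    attached <- max(L + 1L, 1L)
    # attach every remaining compound to a random already-attached one
    for (ci in seq_len(n_compounds)[-seq_len(attached)]) {
      anchor <- comp[sample.int(ci - 1L, 1L)]
      e <- e + 1L
      if (runif(1) < 0.5) {
        src[e] <- anchor
        tgt[e] <- comp[ci]
      } else {
        src[e] <- comp[ci]
        tgt[e] <- anchor
      }
    }
    # leftover reactions: random extra edges between distinct compounds
    while (e < n_reactions) {
      uv <- sample.int(n_compounds, 2L)
      e <- e + 1L
      src[e] <- comp[uv[1L]]
      tgt[e] <- comp[uv[2L]]
    }
    network <- tibble::tibble(
      reaction_id = rid, source = src, target = tgt,
      reversible = runif(n_reactions) < p_reversible
    )
    list(network = network, planted = rid[seq_len(L)])
  })
}

#' Mean shift reaching a target two-sample significance
#'
#' Given a baseline Gaussian `Normal(mu, sigma^2)` and `n_per_group`
#' subjects per group, returns the shifted mean `mu'` such that the
#' expected two-sample t statistic sits exactly at the two-sided critical
#' boundary of level `effect_alpha`:
#' `mu' = mu + t_crit * sigma * sqrt(2 / n_per_group)` with `t_crit` the
#' two-sided Student-t critical value on `2 * n_per_group - 2` degrees of
#' freedom. This operationalizes "shift the mean until the difference is
#' significant at level alpha".
#'
#' @param mu,sigma Baseline mean(s) and standard deviation(s); vectorized.
#' @param n_per_group Subjects per group.
#' @param effect_alpha Two-sided target level.
#' @return Shifted mean(s) `mu'`.
#' @export
effect_shift <- function(mu, sigma, n_per_group, effect_alpha) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  stopifnot(n_per_group >= 2, effect_alpha > 0, effect_alpha < 1)
  tcrit <- qt(1 - effect_alpha / 2, df = 2 * n_per_group - 2)
  mu + tcrit * sigma * sqrt(2 / n_per_group)
}

#' Simulate a reaction-by-sample abundance matrix with a planted chain
#'
#' Every reaction gets a Gaussian abundance distribution whose mean comes
#' from `config$baseline_means` and whose standard deviation is
#' `config$rsd * mean`. Non-planted reactions draw all samples from that
#' one distribution; planted reactions draw group-2 samples from it and
#' group-1 samples from the shifted distribution of [effect_shift()], so
#' the planted chain is enriched in group 1. Draws are truncated at zero
#' (abundances cannot be negative).
#'
#' @param network Network tibble.
#' @param planted Reaction ids of the planted chain (must form a valid
#'   chain in `network`; may be empty for a null dataset).
#' @param config A [simulation_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A `simulated_dataset` list: `network`, `abundance` (tibble),
#'   `groups` (tibble; groups `G1`, `G2`), `planted`, `config`.
#' @export
simulate_abundance <- function(network, planted, config = simulation_config(),
                               seed = config$seed) {
  network <- validate_network(network)
  if (length(planted) > 0L) {
    stopifnot(all(planted %in% network$reaction_id))
    if (!is_valid_chain(network, planted)) {
      stop("planted reactions do not form a valid chain", call. = FALSE)
    }
  }
  r <- nrow(network)
  n <- config$n_per_group
  with_seed_if(seed, {
    bm <- config$baseline_means
    mu <- if (length(bm) == 2L) {
      10^runif(r, log10(bm[1L]), log10(bm[2L]))
    } else {
      sample(bm, r, replace = TRUE)
    }
    sigma <- config$rsd * mu
    X <- matrix(rnorm(r * 2L * n, mean = mu, sd = sigma), nrow = r)
    pl <- match(planted, network$reaction_id)
    if (length(pl) > 0L) {
      mu_shift <- effect_shift(mu[pl], sigma[pl], n, config$effect_alpha)
      X[pl, seq_len(n)] <- rnorm(
        length(pl) * n,
        mean = mu_shift, sd = sigma[pl]
      )
    }
    X <- pmax(X, 0)
    samples <- sprintf("S%02d", seq_len(2L * n))
    colnames(X) <- samples
    abundance <- dplyr::bind_cols(
      tibble::tibble(reaction_id = network$reaction_id),
      tibble::as_tibble(as.data.frame(X))
    )
    groups <- tibble::tibble(
      sample_id = samples,
      group = rep(c("G1", "G2"), each = n)
    )
    structure(
      list(
        network = network, abundance = abundance, groups = groups,
        planted = planted, config = config
      ),
      class = "simulated_dataset"
    )
  })
}

#' Simulate a full planted-signal dataset
#'
#' Convenience wrapper: simulates the network with an embedded chain of
#' `config$planted_length` reactions, then the abundance matrix on top of
#' it.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A `simulated_dataset`; see [simulate_abundance()].
#' @export
simulate_dataset <- function(config = simulation_config(),
                             seed = config$seed) {
  with_seed_if(seed, {
    net <- simulate_network(
      config$n_compounds, config$n_reactions, config$planted_length,
      p_reversible = config$p_reversible
    )
    simulate_abundance(net$network, net$planted, config, seed = NULL)
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(
    "<simulated_dataset> ", nrow(x$network), " reactions x ",
    nrow(x$groups), " samples; planted chain of ", length(x$planted),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Complete compound graph
#'
#' A network with one reaction between every pair of `n_compounds`
#' compounds: the densely connected topology on which random high-weight
#' edges always assemble into a high-scoring subnetwork, used to study the
#' structural selection bias that `p_struct` corrects.
#'
#' @param n_compounds Number of compounds.
#' @param p_reversible Reversibility probability.
#' @param seed Optional seed.
#' @return Network tibble with `choose(n_compounds, 2)` reactions.
#' @export
complete_network <- function(n_compounds, p_reversible = 0.5, seed = NULL) {
  comp <- sprintf("C%04d", seq_len(n_compounds))
  pairs <- utils::combn(n_compounds, 2L)
  m <- ncol(pairs)
  with_seed_if(seed, {
    flip <- runif(m) < 0.5
    tibble::tibble(
      reaction_id = sprintf("R%04d", seq_len(m)),
      source = ifelse(flip, comp[pairs[2L, ]], comp[pairs[1L, ]]),
      target = ifelse(flip, comp[pairs[1L, ]], comp[pairs[2L, ]]),
      reversible = runif(m) < p_reversible
    )
  })
}

#' ROC curve and AUC of a per-reaction ranking
#'
#' Standard receiver operating characteristic over a reaction ranking
#' against the planted truth set. The AUC is the Mann-Whitney statistic
#' (mid-rank handling of ties): the probability that a random planted
#' reaction outranks a random non-planted one.
#'
#' @param scores A data frame with columns `reaction_id` and `score`
#'   (higher = more likely planted), covering all reactions.
#' @param planted Character vector of truly planted reaction ids
#'   (non-empty).
#' @return A `roc_eval` list: `auc` and `curve` (tibble of `fpr`, `tpr`
#'   points, one per distinct score threshold, descending).
#' @export
evaluate_roc <- function(scores, planted) {
  if (length(planted) == 0L) {
    stop("truth set is empty", call. = FALSE)
  }
  stopifnot(all(c("reaction_id", "score") %in% names(scores)))
  truth <- scores$reaction_id %in% planted
  if (!any(truth) || all(truth)) {
    stop("scores must cover both planted and non-planted reactions",
      call. = FALSE
    )
  }
  s <- scores$score
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  rk <- rank(s) # mid-ranks for ties
  auc <- (sum(rk[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(truth[ord])
  fp <- cumsum(!truth[ord])
  last <- !duplicated(s[ord], fromLast = TRUE) # one point per threshold
  curve <- tibble::tibble(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  structure(list(auc = auc, curve = curve), class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat("<roc_eval> AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Assign reactions to synthetic pathway blocks
#'
#' Partitions reactions (in network edge order) into contiguous blocks of
#' `block_size`, emulating curated pathway "containers". The block boundary
#' is placed in the middle of the planted chain, so the planted signal
#' straddles two containers — the scenario in which container-level
#' aggregate tests dilute the signal.
#'
#' @param network Network tibble.
#' @param planted Planted reaction ids (may be empty; blocks then start at
#'   the first edge).
#' @param block_size Reactions per block.
#' @return Tibble with `reaction_id` and `pathway` (block label).
#' @export
assign_pathway_blocks <- function(network, planted, block_size = 20) {
  m <- nrow(network)
  idx <- seq_len(m)
  offset <- 0L
  if (length(planted) > 0L) {
    pos <- match(planted, network$reaction_id)
    pmid <- sort(pos)[ceiling(length(pos) / 2)]
    offset <- (block_size - pmid %% block_size) %% block_size
  }
  block <- (idx - 1L + offset) %/% block_size
  tibble::tibble(
    reaction_id = network$reaction_id,
    pathway = sprintf("P%03d", block + 1L)
  )
}

#' Baseline per-reaction detection scores
#'
#' The two reference methods against which the subnetwork search is
#' benchmarked: (a) per-reaction testing alone — each reaction scored by
#' `1 - p` from its own two-sample test; (b) pathway-aggregate testing —
#' counts are summed within predefined pathway blocks, each block is tested
#' as a unit, and every member reaction inherits `1 - p` of its block.
#'
#' @param dataset A `simulated_dataset` (or any list with `network`,
#'   `abundance`, `groups`, `planted`).
#' @param config A [test_config()] for the underlying tests.
#' @param blocks Optional explicit `reaction_id`/`pathway` assignment;
#'   defaults to [assign_pathway_blocks()] with the planted chain straddling
#'   a block boundary.
#' @param block_size Passed to [assign_pathway_blocks()].
#' @return Tibble with `reaction_id`, `reaction_test` and
#'   `pathway_aggregate` score columns (each usable with [evaluate_roc()]).
#' @export
baseline_scores <- function(dataset, config = test_config(), blocks = NULL,
                            block_size = 20) {
  stats <- compute_reaction_stats(dataset$abundance, dataset$groups, config)
  blocks <- blocks %||%
    assign_pathway_blocks(dataset$network, dataset$planted, block_size)
  if (!all(stats$reaction_id %in% blocks$reaction_id)) {
    missing_blk <- setdiff(stats$reaction_id, blocks$reaction_id)
    stop("reaction(s) without a pathway block: ",
      paste(utils::head(missing_blk, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  block_ab <- dataset$abundance |>
    dplyr::inner_join(blocks, by = "reaction_id") |>
    dplyr::select(-"reaction_id") |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), sum),
      .by = "pathway"
    ) |>
    dplyr::rename(reaction_id = "pathway")
  block_stats <- compute_reaction_stats(block_ab, dataset$groups, config) |>
    dplyr::select(pathway = "reaction_id", block_p = "p")
  stats |>
    dplyr::left_join(blocks, by = "reaction_id") |>
    dplyr::left_join(block_stats, by = "pathway") |>
    dplyr::transmute(
      reaction_id = .data$reaction_id,
      reaction_test = 1 - .data$p,
      pathway_aggregate = 1 - .data$block_p
    )
}

#' Per-reaction ranking derived from subnetwork discovery
#'
#' Turns a discovery result into a reaction-level detection score for ROC
#' benchmarking: reactions inside a reported significant subnetwork are
#' scored by `1 - p_abund` of their subnetwork; all other reactions fall
#' back to `1 - p` of their own test.
#'
#' @param discovery A `subnet_discovery` object.
#' @return Tibble with `reaction_id` and `score`.
#' @export
discovery_scores <- function(discovery) {
  stats <- discovery$stats
  out <- tibble::tibble(
    reaction_id = stats$reaction_id,
    score = 1 - stats$p
  )
  for (res in discovery$results) {
    hit <- out$reaction_id %in% res$subnetwork$edges
    out$score[hit] <- 1 - res$p_abund
  }
  out
}
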