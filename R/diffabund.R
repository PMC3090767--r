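#' Configuration of the per-reaction differential-abundance test
#'
#' Controls the two-sample test applied to each reaction. The statistic is
#' always Welch's t on per-sample relative abundances; the null distribution
#' is either a permutation null (label reshuffling, the default) or the
#' t-distribution with Satterthwaite degrees of freedom.
#'
#' With the permutation engine and two small groups, all distinct
#' group-label assignments are enumerated exactly whenever their number is
#' at most `exhaustive_cap` (with 5 samples per group there are only
#' `choose(10, 5) = 252`); otherwise `b` Monte-Carlo label permutations are
#' drawn and the p-value uses the add-one rule `(r + 1) / (b + 1)`, which
#' keeps p strictly positive so the Z-transform stays finite. p-values are
#' floored at `1 / (b + 1)` (Monte-Carlo and t-distribution engines) or at
#' the natural `1 / n_assignments` resolution (exhaustive engine).
#'
#' @param engine `"permutation"` or `"tdist"`.
#' @param b Number of Monte-Carlo permutations (when not exhaustive).
#' @param exhaustive Allow exact enumeration of label assignments?
#' @param exhaustive_cap Largest number of distinct assignments that will be
#'   enumerated exactly.
#' @param seed Optional integer seed for the Monte-Carlo draws.
#' @return A `test_config` list.
#' @export
test_config <- function(engine = c("permutation", "tdist"), b = 1000,
                        exhaustive = TRUE, exhaustive_cap = 10000,
                        seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(b >= 1, exhaustive_cap >= 1)
  structure(
    list(
      engine = engine, b = as.integer(b), exhaustive = isTRUE(exhaustive),
      exhaustive_cap = as.integer(exhaustive_cap), seed = seed
    ),
    class = "test_config"
  )
}

#' Convert counts to per-sample relative abundances
#'
#' Divides every column (sample) of the abundance matrix by its total, so
#' each column sums to one. A sample with an all-zero column has no reads
#' and cannot be normalized.
#'
#' @param abundance Abundance tibble (`reaction_id` + one numeric column per
#'   sample).
#' @return Abundance tibble of the same shape with column sums equal to 1.
#' @export
relative_abundance <- function(abundance) {
  X <- abundance_matrix(abundance)
  tot <- colSums(X)
  if (any(tot <= 0)) {
    stop("sample '", colnames(X)[which(tot <= 0)[1L]],
      "' has zero total abundance and cannot be normalized",
      call. = FALSE
    )
  }
  X <- sweep(X, 2L, tot, "/")
  out <- tibble::as_tibble(as.data.frame(X))
  dplyr::bind_cols(abundance[, 1L, drop = FALSE], out)
}

# abundance tibble -> numeric matrix with reaction rownames
abundance_matrix <- function(abundance) {
  stopifnot(names(abundance)[1L] == "reaction_id")
  X <- as.matrix(abundance[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("abundance values must be numeric", call. = FALSE)
  if (any(X < 0)) stop("abundance values must be non-negative", call. = FALSE)
  rownames(X) <- abundance$reaction_id
  X
}

# All C(n, n1) group-1 membership indicators, as an n x M 0/1 matrix.
all_assignments <- function(n, n1) {
  comb <- utils::combn(n, n1)
  A <- matrix(0, n, ncol(comb))
  A[cbind(as.vector(comb), rep(seq_len(ncol(comb)), each = n1))] <- 1
  A
}

# B random group-1 membership indicators (uniform over assignments, which is
# what uniformly permuting the label vector induces).
random_assignments <- function(n, n1, b) {
  idx <- replicate(b, sample.int(n, n1))
  A <- matrix(0, n, b)
  A[cbind(as.vector(idx), rep(seq_len(b), each = n1))] <- 1
  A
}

# Welch t statistics for every row of X under every column of the membership
# matrix A (n x M of 0/1 group-1 indicators). Degenerate cells (both group
# variances numerically zero) give t = 0 when the mean difference is also
# numerically zero and +/-Inf otherwise. Returns list(t, df, m1, m2).
welch_t_matrix <- function(X, A) {
  n <- ncol(X)
  n1 <- colSums(A)
  n2 <- n - n1
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  X2 <- X * X
  S1 <- X %*% A
  Q1 <- X2 %*% A
  St <- rowSums(X)
  Qt <- rowSums(X2)
  S2 <- St - S1
  Q2 <- Qt - Q1
  m1 <- sweep(S1, 2L, n1, "/")
  m2 <- sweep(S2, 2L, n2, "/")
  v1 <- sweep(Q1 - sweep(S1^2, 2L, n1, "/"), 2L, n1 - 1, "/")
  v2 <- sweep(Q2 - sweep(S2^2, 2L, n2, "/"), 2L, n2 - 1, "/")
  # numerical floor: a constant row yields a tiny negative/positive variance
  # through cancellation; treat anything below ~machine noise as exact zero
  msq <- Qt / n
  v1[v1 < 1e-12 * msq] <- 0
  v2[v2 < 1e-12 * msq] <- 0
  d <- m1 - m2
  d[abs(d) <= 1e-8 * sqrt(msq)] <- 0
  se2 <- sweep(v1, 2L, n1, "/") + sweep(v2, 2L, n2, "/")
  t <- d / sqrt(se2)
  zero_se <- se2 == 0
  if (any(zero_se)) {
    t[zero_se] <- ifelse(d[zero_se] == 0, 0, sign(d[zero_se]) * Inf)
  }
  a1 <- sweep(v1, 2L, n1, "/")
  a2 <- sweep(v2, 2L, n2, "/")
  den <- sweep(a1^2, 2L, n1 - 1, "/") + sweep(a2^2, 2L, n2 - 1, "/")
  df <- se2^2 / den
  df[!is.finite(df)] <- 1
  list(t = t, df = df, m1 = m1, m2 = m2)
}

#' Two-sample permutation p-value for a single reaction
#'
#' Two-sided p-value for the difference in mean abundance between two
#' vectors of per-sample values, using Welch's t as the statistic. See
#' [test_config()] for the null options. Permutations tying the observed
#' statistic (`|t_perm| >= |t_obs|`) count as extreme, which is
#' conservative. Two identical constant groups give p = 1; zero variance
#' with unequal means is treated as an infinite statistic and yields the
#' smallest attainable p-value.
#'
#' @param x,y Numeric vectors of length at least 2 (values in group 1 and
#'   group 2).
#' @param config A [test_config()].
#' @return A single p-value in (0, 1].
#' @export
reaction_pvalue <- function(x, y, config = test_config()) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  X <- matrix(c(x, y), nrow = 1L)
  memb <- c(rep(1, length(x)), rep(0, length(y)))
  as.numeric(pvalues_for_matrix(X, memb, config)$p)
}

# Core routine shared by reaction_pvalue() and compute_reaction_stats():
# p-values (and observed means / signs) for every row of X given the
# observed group-1 membership vector. Returns list(p, m1, m2, floor).
pvalues_for_matrix <- function(X, memb, config) {
  n <- ncol(X)
  n1 <- sum(memb)
  use_exhaustive <- config$engine == "permutation" && config$exhaustive &&
    choose(n, n1) <= config$exhaustive_cap
  if (config$engine == "tdist") {
    wt <- welch_t_matrix(X, matrix(memb, ncol = 1L))
    p <- 2 * pt(abs(wt$t), wt$df, lower.tail = FALSE)
    floor_p <- 1 / (config$b + 1)
    p <- pmin(pmax(p, floor_p), 1)
    return(list(
      p = as.numeric(p), m1 = as.numeric(wt$m1), m2 = as.numeric(wt$m2),
      floor = floor_p
    ))
  }
  if (use_exhaustive) {
    A <- all_assignments(n, n1)
    wt <- welch_t_matrix(X, A)
    j0 <- observed_column(A, memb)
    tobs <- abs(wt$t[, j0])
    p <- rowMeans(abs(wt$t) >= tobs * (1 - 1e-12))
    return(list(
      p = as.numeric(p), m1 = as.numeric(wt$m1[, j0]),
      m2 = as.numeric(wt$m2[, j0]), floor = 1 / ncol(A)
    ))
  }
  A <- with_seed_if(config$seed, random_assignments(n, n1, config$b))
  A <- cbind(memb, A)
  wt <- welch_t_matrix(X, A)
  tobs <- abs(wt$t[, 1L])
  r <- rowSums(abs(wt$t[, -1L, drop = FALSE]) >= tobs * (1 - 1e-12))
  p <- (r + 1) / (config$b + 1)
  list(
    p = as.numeric(p), m1 = as.numeric(wt$m1[, 1L]),
    m2 = as.numeric(wt$m2[, 1L]), floor = 1 / (config$b + 1)
  )
}

# column of A equal to the observed membership vector
observed_column <- function(A, memb) {
  hit <- which(colSums(A != memb) == 0L)
  if (length(hit) == 0L) stop("internal: observed assignment not enumerated")
  hit[1L]
}

#' Convert a two-sided p-value to a signed Z-score
#'
#' `z = sign * qnorm(1 - p / 2)` where the sign is positive when the
#' reaction's mean is higher in group 1, negative when higher in group 2,
#' and zero (hence z = 0) when the means are equal. `p = 1` maps to `z = 0`;
#' callers must floor p upstream (see [test_config()]) so z is finite.
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param mean_g1,mean_g2 Group mean abundances used only for the sign.
#' @return Signed Z-score(s).
#' @export
p_to_z <- function(p, mean_g1, mean_g2) {
  if (any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  sgn <- sign(mean_g1 - mean_g2)
  sgn * qnorm(1 - p / 2)
}

#' Per-reaction differential-abundance statistics
#'
#' Runs the two-sample test of [reaction_pvalue()] on every row of the
#' abundance matrix and converts each p-value to a signed Z-score (the edge
#' weight used by the subnetwork search). Reactions whose raw counts are
#' zero in every sample get p = 1 and z = 0. By default counts are first
#' converted to per-sample relative abundances.
#'
#' @param abundance Abundance tibble.
#' @param groups Groups tibble or [group_design()].
#' @param config A [test_config()].
#' @param normalize Convert to relative abundances first?
#' @return A tibble with one row per reaction: `reaction_id`, `mean_g1`,
#'   `mean_g2` (group means on the analysis scale), `p`, `z`, `sign`.
#' @export
compute_reaction_stats <- function(abundance, groups, config = test_config(),
                                   normalize = TRUE) {
  design <- group_design(groups)
  X <- abundance_matrix(abundance)
  missing_samples <- setdiff(colnames(X), design$sample_id)
  if (length(missing_samples) > 0L) {
    stop("sample(s) not assigned to a group: ",
      paste(missing_samples, collapse = ", "),
      call. = FALSE
    )
  }
  lab <- design$group[match(colnames(X), design$sample_id)]
  memb <- as.numeric(lab == design$g1)
  zero_row <- rowSums(X) == 0
  if (normalize) {
    tot <- colSums(X)
    if (any(tot <= 0)) {
      stop("sample '", colnames(X)[which(tot <= 0)[1L]],
        "' has zero total abundance and cannot be normalized",
        call. = FALSE
      )
    }
    X <- sweep(X, 2L, tot, "/")
  }
  res <- pvalues_for_matrix(X, memb, config)
  p <- pmin(pmax(res$p, res$floor), 1)
  p[zero_row] <- 1
  z <- p_to_z(p, res$m1, res$m2)
  z[zero_row] <- 0
  tibble::tibble(
    reaction_id = rownames(X),
    mean_g1 = res$m1, mean_g2 = res$m2,
    p = p, z = z, sign = sign(z)
  )
}
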