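#' Tidy a discovery result
#'
#' One row per reported subnetwork, ranked by `p_abund` (ties by
#' `p_struct`, then larger absolute score).
#'
#' @param x A `subnet_discovery` object.
#' @param ... Unused.
#' @return Tibble with `rank`, `p_abund`, `p_struct`, `k`, `score`,
#'   `enriched_in` and a `reactions` list-column of member reaction ids.
#' @exportS3Method generics::tidy
tidy.subnet_discovery <- function(x, ...) {
  if (length(x$results) == 0L) {
    return(tibble::tibble(
      rank = integer(), p_abund = numeric(), p_struct = numeric(),
      k = integer(), score = numeric(), enriched_in = character(),
      reactions = list()
    ))
  }
  tibble::tibble(
    p_abund = purrr::map_dbl(x$results, "p_abund"),
    p_struct = purrr::map_dbl(x$results, "p_struct"),
    k = purrr::map_int(x$results, ~ .x$subnetwork$k),
    score = purrr::map_dbl(x$results, "score"),
    enriched_in = purrr::map_chr(x$results, "enriched_in"),
    reactions = purrr::map(x$results, ~ .x$subnetwork$edges)
  ) |>
    dplyr::arrange(
      .data$p_abund, .data$p_struct, dplyr::desc(abs(.data$score))
    ) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}

#' One-line summary of a discovery run
#'
#' @param x A `subnet_discovery` object.
#' @param ... Unused.
#' @return A one-row tibble: number of subnetworks, reactions covered,
#'   search mode, permutation budgets and thresholds.
#' @exportS3Method generics::glance
glance.subnet_discovery <- function(x, ...) {
  members <- unique(unlist(purrr::map(x$results, ~ .x$subnetwork$edges)))
  tibble::tibble(
    n_subnetworks = length(x$results),
    n_member_reactions = length(members),
    n_reactions_tested = nrow(x$stats),
    mode = x$mode,
    b_abund = x$config$b_abund,
    b_struct = x$config$b_struct,
    alpha_abund = x$config$alpha_abund,
    alpha_struct = x$config$alpha_struct
  )
}

#' Plot a discovery result
#'
#' Scatter of reported subnetworks: size against aggregate score, coloured
#' by the enriched group and labelled by rank.
#'
#' @param object A `subnet_discovery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.subnet_discovery <- function(object, ...) {
  tab <- tidy(object)
  if (nrow(tab) == 0L) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no significant subnetworks") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$k, y = .data$score, colour = .data$enriched_in,
      label = .data$rank
    )
  ) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p_abund))) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(
      x = "subnetwork size (reactions)", y = "aggregate Z score",
      colour = "enriched in", size = "-log10 p_abund"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `roc_eval` from [evaluate_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of per-reaction p-values
#'
#' Quick diagnostic of the per-reaction test: under an exchangeable null
#' the histogram should be flat.
#'
#' @param stats Per-reaction statistics tibble from
#'   [compute_reaction_stats()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(stats, bins = 20) {
  ggplot2::ggplot(stats, ggplot2::aes(.data$p)) +
    ggplot2::geom_histogram(
      bins = bins, boundary = 0, fill = "steelblue", colour = "white"
    ) +
    ggplot2::labs(x = "per-reaction p-value", y = "reactions") +
    ggplot2::theme_minimal()
}
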