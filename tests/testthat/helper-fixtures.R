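# Shared builders for small deterministic fixtures.

# simple directed path C1 -> C2 -> ... -> C(n+1), edges e01..e<n>
path_network <- function(n = 5, reversible = FALSE) {
  tibble::tibble(
    reaction_id = sprintf("e%02d", seq_len(n)),
    source = sprintf("C%d", seq_len(n)),
    target = sprintf("C%d", seq_len(n) + 1),
    reversible = rep(reversible, length.out = n)
  )
}

# abundance tibble with named sample columns from a numeric matrix
abundance_from_matrix <- function(X) {
  tibble::as_tibble(cbind(
    data.frame(reaction_id = rownames(X), stringsAsFactors = FALSE),
    as.data.frame(X)
  ))
}

# two-group design over 2n samples S01..S<2n>
toy_groups <- function(n_per_group = 5) {
  n <- 2 * n_per_group
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("G1", "G2"), each = n_per_group)
  )
}

# random small network for property tests (duplicate-free edge ids)
random_network <- function(n_comp, n_edge) {
  tibble::tibble(
    reaction_id = sprintf("e%02d", seq_len(n_edge)),
    source = sprintf("C%d", sample(n_comp, n_edge, replace = TRUE)),
    target = sprintf("C%d", sample(n_comp, n_edge, replace = TRUE)),
    reversible = sample(c(TRUE, FALSE), n_edge, replace = TRUE)
  )
}
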