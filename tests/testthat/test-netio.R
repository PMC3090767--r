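test_that("network files round-trip exactly, including edge order", {
  net <- tibble::tibble(
    reaction_id = c("R2", "R1", "R3"),
    source = c("Cb", "Ca", "Cb"),
    target = c("Ca", "Cb", "Cb"), # self-loop allowed
    reversible = c(TRUE, FALSE, TRUE)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  expect_identical(read_network(f), net)
})

test_that("read_network skips comments and blank lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# a comment", "", "R1 C1 C2 0", "   ", "\t# indented comment",
    "R2\tC2\tC3\t1"
  ), f)
  net <- read_network(f)
  expect_equal(net$reaction_id, c("R1", "R2"))
  expect_equal(net$reversible, c(FALSE, TRUE))
})

test_that("read_network reports malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header", "R1 C1 C2 0", "R2 C2 C3"), f)
  expect_error(read_network(f), "line 3.*4 fields")

  writeLines(c("R1 C1 C2 yes"), f)
  expect_error(read_network(f), "line 1.*0 or 1")
})

test_that("read_network rejects duplicate reaction ids, naming the lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R1 C1 C2 0", "R2 C2 C3 0", "R1 C3 C4 1"), f)
  expect_error(read_network(f), "duplicate reaction id 'R1'.*1, 3")
})

test_that("read_network errors on a missing file and handles empty files", {
  expect_error(read_network(file.path(tempdir(), "no-such-file")), "not found")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", f)
  expect_equal(nrow(read_network(f)), 0L)
})

test_that("validate_network enforces the invariants", {
  net <- path_network(3)
  expect_identical(validate_network(net), net)
  expect_error(validate_network(net[-1L]), "missing column")
  bad <- net
  bad$reaction_id[2] <- "e01"
  expect_error(validate_network(bad), "duplicate reaction id 'e01'")
  bad <- net
  bad$source[1] <- NA
  expect_error(validate_network(bad), "missing values")
})

test_that("abundance files round-trip and reject malformed cells", {
  X <- matrix(c(1, 2.5, 0, 4), 2, 2,
    dimnames = list(c("R1", "R2"), c("S1", "S2"))
  )
  ab <- abundance_from_matrix(X)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(ab, f)
  expect_equal(read_abundance(f), ab)

  writeLines(c("reaction_id\tS1\tS1", "R1\t1\t2"), f)
  expect_error(read_abundance(f), "duplicated sample column 'S1'")

  writeLines(c("reaction_id\tS1", "R1\t1", "R1\t2"), f)
  expect_error(read_abundance(f), "duplicated reaction id 'R1'")

  writeLines(c("reaction_id\tS1\tS2", "R1\t1\tx"), f)
  expect_error(read_abundance(f), "reaction 'R1', sample 'S2'")

  writeLines(c("reaction_id\tS1", "R1\t-3"), f)
  expect_error(read_abundance(f), "negative abundance.*'R1', sample 'S1'")
})

test_that("group files round-trip with or without a header", {
  g <- toy_groups(2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_groups(g, f)
  expect_equal(read_groups(f), g)
  writeLines(c("S01\tG1", "S02\tG1", "S03\tG2", "S04\tG2"), f)
  expect_equal(read_groups(f), g)
})

test_that("group_design normalizes labels and validates the design", {
  g <- toy_groups(2)
  d <- group_design(g)
  expect_s3_class(d, "group_design")
  expect_equal(d$g1, "G1")
  expect_equal(d$g2, "G2")
  # explicit role swap
  d2 <- group_design(g, g1 = "G2")
  expect_equal(d2$g1, "G2")
  expect_equal(d2$g2, "G1")
  # idempotent on an existing design
  expect_identical(group_design(d), d)

  expect_error(group_design(dplyr::mutate(g, group = "G1")), "exactly two")
  expect_error(
    group_design(tibble::tibble(
      sample_id = c("a", "b", "c"), group = c("G1", "G1", "G2")
    )),
    "at least two samples"
  )
  expect_error(
    group_design(dplyr::mutate(g, sample_id = "S01")),
    "duplicated sample id"
  )
  expect_error(group_design(g, g1 = "nope"), "distinct group labels")
})

make_hits <- function(lines, file) {
  writeLines(lines, file)
  file
}

test_that("counts_from_hits picks best hits and applies strict filters", {
  hits_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  # query q1: best hit by bitscore is g2; q2's best (g3) fails identity filter
  # q3 maps to nothing
  make_hits(c(
    "q1\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    "q1\tg2\t80\t100\t0\t0\t1\t100\t1\t100\t1e-40\t200",
    "q2\tg3\t50\t100\t0\t0\t1\t100\t1\t100\t1e-30\t150",
    "q3\tg9\t95\t100\t0\t0\t1\t100\t1\t100\t1e-30\t150"
  ), hits_f)
  writeLines(c("g1\tRA", "g2\tRB", "g9\tRZ"), map_f)

  ab <- counts_from_hits(c(sampleA = hits_f), map_f)
  # q2 dropped: identity 50 is NOT > 50 (strict)
  expect_equal(attr(ab, "n_dropped"), 1L)
  expect_equal(ab$reaction_id, c("RB", "RZ"))
  expect_equal(ab$sampleA, c(1, 1))
  expect_equal(nrow(attr(ab, "unmapped")), 0L)
})

test_that("counts_from_hits e-value and bitscore filters are strict too", {
  hits_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  make_hits(c(
    "q1\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-5\t120", # evalue == max: drop
    "q2\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t50" # bitscore == min: drop
  ), hits_f)
  writeLines("g1\tRA", map_f)
  ab <- counts_from_hits(c(s = hits_f), map_f)
  expect_equal(attr(ab, "n_dropped"), 2L)
  expect_equal(nrow(ab), 0L)
})

test_that("multi-mapping genes count once per reaction or fractionally", {
  hits_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  make_hits(
    "q1\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    hits_f
  )
  writeLines(c("g1\tRA", "g1\tRB"), map_f)

  once <- counts_from_hits(c(s = hits_f), map_f)
  expect_equal(once$s[match(c("RA", "RB"), once$reaction_id)], c(1, 1))

  frac <- counts_from_hits(c(s = hits_f), map_f, multi = "fractional")
  expect_equal(frac$s[match(c("RA", "RB"), frac$reaction_id)], c(0.5, 0.5))
})

test_that("unmapped best hits are tallied, not errors", {
  hits_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  make_hits(c(
    "q1\tgX\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    "q2\tgX\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    "q3\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120"
  ), hits_f)
  writeLines("g1\tRA", map_f)
  ab <- counts_from_hits(c(s = hits_f), map_f)
  um <- attr(ab, "unmapped")
  expect_equal(um$subject, "gX")
  expect_equal(um$n_queries, 2L)
  expect_equal(ab$reaction_id, "RA")
})

test_that("single 13-column hits file carries its own sample column", {
  hits_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  make_hits(c(
    "sa\tq1\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    "sb\tq1\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120",
    "sb\tq2\tg1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-30\t120"
  ), hits_f)
  writeLines("g1\tRA", map_f)
  ab <- counts_from_hits(hits_f, map_f)
  expect_equal(names(ab), c("reaction_id", "sa", "sb"))
  expect_equal(unlist(ab[1, c("sa", "sb")], use.names = FALSE), c(1, 2))
})

test_that("write_report emits ranked tables and DOT files", {
  net <- path_network(4)
  results <- tibble::tibble(
    p_abund = c(0.02, 0.001),
    p_struct = c(0.03, 0.01),
    k = c(2L, 2L),
    score = c(2.5, 4),
    enriched_in = c("G1", "G2"),
    reactions = list(c("e01", "e02"), c("e03", "e04"))
  )
  stats <- tibble::tibble(
    reaction_id = net$reaction_id, mean_g1 = 1, mean_g2 = 1,
    p = 0.5, z = 0, sign = 0
  )
  out <- withr::local_tempdir()
  files <- write_report(results, stats, out, network = net)
  expect_true(all(file.exists(files)))

  sub <- readr::read_tsv(file.path(out, "subnetworks.tsv"),
    show_col_types = FALSE
  )
  # lowest p_abund first
  expect_equal(sub$rank, 1:2)
  expect_equal(sub$p_abund, c(0.001, 0.02))
  expect_equal(sub$reactions, c("e03,e04", "e01,e02"))

  rx <- readr::read_tsv(file.path(out, "reactions.tsv"),
    show_col_types = FALSE
  )
  expect_equal(rx$subnetwork_rank[match(c("e01", "e03"), rx$reaction_id)],
    c(2, 1))
  expect_true(file.exists(file.path(out, "subnetwork_01.dot")))
})

test_that("write_report refuses unrankable (NaN) p-values", {
  results <- tibble::tibble(
    p_abund = NaN, p_struct = 0.01, k = 1L, score = 1,
    enriched_in = "G1", reactions = list("e01")
  )
  stats <- tibble::tibble(
    reaction_id = "e01", mean_g1 = 1, mean_g2 = 1, p = 0.5, z = 0, sign = 0
  )
  expect_error(
    write_report(results, stats, withr::local_tempdir(), dot = FALSE),
    "NaN"
  )
})

test_that("DOT output honors direction and validates membership", {
  net <- path_network(2, reversible = c(FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".dot")
  write_subnetwork_dot(net, c("e01", "e02"), f)
  txt <- readLines(f)
  expect_match(txt[1], "digraph")
  expect_match(txt[2], "\"C1\" -> \"C2\"")
  expect_false(grepl("dir=both", txt[2]))
  expect_match(txt[3], "dir=both")
  expect_error(
    write_subnetwork_dot(net, "nope", f),
    "not present in network: nope"
  )
})

test_that("empty discovery still writes a valid header-only report", {
  net <- path_network(2)
  ab <- abundance_from_matrix(matrix(1,
    2, 4,
    dimnames = list(net$reaction_id, sprintf("S%02d", 1:4))
  ))
  d <- discover_subnetworks(
    net, ab, toy_groups(2),
    config = significance_config(b_abund = 19, b_struct = 19, seed = 1)
  )
  expect_length(d$results, 0L)
  out <- withr::local_tempdir()
  write_report(d, path = out)
  sub <- readr::read_tsv(file.path(out, "subnetworks.tsv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(sub), 0L)
  expect_named(
    sub,
    c("rank", "p_abund", "p_struct", "k", "score", "enriched_in", "reactions")
  )
})
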