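test_that("cost files parse, validate and round-trip", {
  txt <- paste(
    "# example cost file",
    "units\ta\tb\tc",
    "a\t0\t1\t5",
    "b\t1\t0\t1",
    "c\t5\t1\t0",
    "duplication\t0.5",
    "insertion\t1.5",
    "deletion\t1.5", sep = "\n")
  cm <- read_cost_file(text = txt)
  expect_s3_class(cm, "cost_model")
  expect_equal(cm$d_M["a", "c"], 5)
  # chain a -> b -> c is cheaper than the direct entry
  expect_equal(cm$d_M_closed["a", "c"], 2)
  expect_equal(cm$c_dup, 0.5)

  # round-trip through the writer preserves the model
  cm2 <- read_cost_file(text = paste(write_cost_file(cm), collapse = "\n"))
  expect_equal(cm2$d_M, cm$d_M)
  expect_equal(c(cm2$c_dup, cm2$c_ins, cm2$c_del),
               c(cm$c_dup, cm$c_ins, cm$c_del))

  # a 2-symbol metric file: closure leaves the matrix unchanged
  cm3 <- read_cost_file(text = paste(
    "units\ta\tb", "a\t0\t1", "b\t1\t0",
    "duplication\t0.5", "insertion\t1.5", "deletion\t1.5", sep = "\n"))
  expect_equal(cm3$d_M_closed, cm3$d_M)
})

test_that("malformed cost files are rejected with informative errors", {
  expect_error(read_cost_file(text = paste(
    "units\ta\tb", "a\t0\t1",
    "duplication\t0.5", "insertion\t1.5", "deletion\t1.5", sep = "\n")),
    "matrix rows")
  expect_error(read_cost_file(text = paste(
    "units\ta\tb", "a\t0\t2", "b\t1\t0",
    "duplication\t0.5", "insertion\t1.5", "deletion\t1.5", sep = "\n")),
    "asymmetric")
  expect_error(read_cost_file(text = paste(
    "units\ta\tb", "a\t0\t1", "b\t1\t0",
    "duplication\t0.5", "insertion\t1.5", "elephants\t1.5", sep = "\n")),
    "deletion")
})

test_that("default cost model respects the event-cost ordering on any alphabet", {
  for (k in c(1, 2, 8, 64)) {
    cm <- default_cost_model(sprintf("u%02d", seq_len(k)))
    expect_equal(dim(cm$d_M), c(k, k))
    expect_true(all(diag(cm$d_M) == 0))
    if (k > 1) expect_true(all(cm$d_M[upper.tri(cm$d_M)] == 1))
    expect_lt(cm$c_dup, min(cm$d_M[cm$d_M > 0], cm$c_ins, cm$c_del))
    expect_equal(cm$d_M_closed, cm$d_M)
  }
  # the MSY1-style 8-code alphabet with multi-character symbols
  cm <- default_cost_model(c("0", "1", "1a", "2", "3", "3a", "4", "4a"))
  expect_equal(length(cm$alphabet), 8)
  expect_equal(cm$d_M["1a", "4a"], 1)
  expect_error(default_cost_model(character(0)), "empty")
  expect_error(default_cost_model(c("a", "@x")), "reserved")
})

test_that("min-plus closure is idempotent, non-increasing and metric", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      k <- sample(2:6, 1)
      ab <- letters[seq_len(k)]
      d <- matrix(0, k, k, dimnames = list(ab, ab))
      d[upper.tri(d)] <- stats::runif(k * (k - 1) / 2, 0, 5)
      d <- d + t(d)
      cl <- close_mutation_costs(d)
      expect_true(all(cl <= d + 1e-12))
      expect_equal(close_mutation_costs(cl), cl)
      for (x in 1:k) for (y in 1:k) for (z in 1:k)
        expect_lte(cl[x, z], cl[x, y] + cl[y, z] + 1e-12)
    }
  })
  expect_equal(close_mutation_costs(matrix(0, 1, 1)), matrix(0, 1, 1))
})

test_that("closure agrees with shortest-path distances from igraph", {
  skip_if_not_installed("igraph")
  withr::with_seed(21, {
    k <- 6
    ab <- letters[1:6]
    d <- matrix(0, k, k, dimnames = list(ab, ab))
    d[upper.tri(d)] <- stats::runif(15, 0.1, 4)
    d <- d + t(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(unname(close_mutation_costs(d)),
                 unname(igraph::distances(g)), tolerance = 1e-12)
  })
})

test_that("gradient cost model is a metric equal to its own closure", {
  cm <- gradient_cost_model(letters[1:5], step = 0.5)
  expect_equal(cm$d_M["a", "e"], 2)
  expect_equal(cm$d_M_closed, cm$d_M)
})

test_that("cost model constructor validates its invariants", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cost_model(d, c_dup = 0), "positive")
  expect_error(cost_model(d - 0.5), "zero diagonal|non-negative")
  d2 <- d; d2[1, 2] <- 2
  expect_error(cost_model(d2), "symmetric")
})
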