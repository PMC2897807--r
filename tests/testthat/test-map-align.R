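test_that("run explanations match enumerated split optima", {
  cm <- default_cost_model(c("x", "y"))
  # two duplications from the left seed beat indels
  expect_equal(explain_run("xx", "x", "y", costs = cm)$cost, 1.0)
  cm3 <- default_cost_model(c("x", "y", "z"))
  # three-way tie at 1.5 between left generation, right generation, indel
  expect_equal(explain_run("z", "x", "y", costs = cm3)$cost, 1.5)
  expect_equal(explain_run(character(0), "x", "y", costs = cm)$cost, 0)
  # direction restriction without the needed flank falls back to indels
  expect_equal(explain_run("xx", NULL, "x", mode = "lr", costs = cm)$cost, 3.0)
  # the chosen split re-prices to the reported cost
  er <- explain_run("xxy", "x", "y", costs = cm)
  regen <- flank_generation_cost("x", er$gen_left, "left", cm) +
    cm$c_del * length(er$indel) +
    flank_generation_cost("y", er$gen_right, "right", cm)
  expect_equal(regen, er$cost)
})

test_that("pairwise alignment reproduces the worked examples", {
  cm <- default_cost_model(c("a", "b"))
  expect_equal(align_pair(mini_map("1", "ab"), mini_map("2", "abb"),
                          cm)$total_cost, 0.5)
  cm3 <- default_cost_model(c("a", "b", "c"))
  A <- mini_map("1", "ab"); B <- mini_map("2", "ccab")
  expect_equal(align_pair(A, B, cm3, mode = "both")$total_cost, 2.0)
  expect_equal(align_pair(A, B, cm3, mode = "lr")$total_cost, 3.0)
  a <- align_pair(mini_map("1", "abab"), mini_map("2", "abab"), cm)
  expect_equal(a$total_cost, 0)
  expect_equal(nrow(a$matches), 4)
  expect_equal(nrow(a$runs), 0)
})

test_that("alignment equals the brute-force matching oracle on small pairs", {
  withr::with_seed(202, {
    strings <- all_strings(c("a", "b"), 3)
    matchings <- list()
    for (rep in 1:3) {
      cm <- random_cost_model(c("a", "b"))
      gen <- make_oracle_gen(cm)
      for (ua in strings) for (ub in strings) {
        key <- paste(length(ua), length(ub))
        if (is.null(matchings[[key]]))
          matchings[[key]] <- monotone_matchings(length(ua), length(ub))
        got <- align_pair(mini_map("A", ua), mini_map("B", ub), cm)$total_cost
        want <- oracle_align_cost(ua, ub, cm, "both", gen, matchings[[key]])
        expect_equal(got, want, tolerance = 1e-9,
                     label = sprintf("align(%s, %s)", paste(ua, collapse = ""),
                                     paste(ub, collapse = "")))
      }
    }
  })
})

test_that("model invariants hold on random pairs", {
  withr::with_seed(303, {
    ab <- c("a", "b", "c")
    for (rep in 1:30) {
      cm <- random_cost_model(ab)
      A <- random_map("A", ab, sample(1:7, 1))
      B <- random_map("B", ab, sample(1:7, 1))
      both <- align_pair(A, B, cm)$total_cost
      # symmetry when c_ins == c_del
      expect_equal(align_pair(B, A, cm)$total_cost, both, tolerance = 1e-9)
      # identity
      expect_equal(align_pair(A, A, cm)$total_cost, 0)
      # direction restriction can only cost more
      expect_gte(align_pair(A, B, cm, "lr")$total_cost, both - 1e-9)
      expect_gte(align_pair(A, B, cm, "rl")$total_cost, both - 1e-9)
      # never worse than pricing both maps entirely as indels
      expect_lte(both, cm$c_del * length(A$units) +
                   cm$c_ins * length(B$units) + 1e-9)
      # recorded per-column and per-run costs re-price the total exactly
      al <- align_pair(A, B, cm)
      expect_equal(sum(al$matches$cost) + sum(al$runs$cost), al$total_cost,
                   tolerance = 1e-9)
    }
  })
})

test_that("all_pairwise produces a symmetric zero-diagonal matrix", {
  cm <- default_cost_model(c("a", "b"))
  maps <- list(mini_map("m1", "ab"), mini_map("m2", "ab"), mini_map("m3", "abb"))
  d <- all_pairwise(maps, cm)
  expect_equal(dim(d), c(3, 3))
  expect_equal(diag(d), setNames(rep(0, 3), c("m1", "m2", "m3")))
  expect_equal(d, t(d))
  expect_equal(d["m1", "m2"], 0)
  expect_equal(d["m1", "m3"], 0.5)
  expect_equal(d["m2", "m3"], 0.5)
  dn <- all_pairwise(maps, cm, normalize = TRUE)
  expect_equal(dn["m1", "m3"], 0.5 / 5)
  expect_error(all_pairwise(list(mini_map("m", "a"), mini_map("m", "b")), cm),
               "duplicate")
  expect_error(all_pairwise(maps[1], cm), "at least 2")
})

test_that("batch pairwise costs agree with individual alignments in every mode", {
  withr::with_seed(99, {
    ab <- c("a", "b", "c")
    cm <- random_cost_model(ab)
    maps <- lapply(1:4, function(i) random_map(paste0("m", i), ab, sample(2:6, 1)))
    for (mode in c("both", "lr", "rl")) {
      d <- all_pairwise(maps, cm, mode)
      for (i in 1:3) for (j in (i + 1):4)
        expect_equal(d[i, j],
                     align_pair(maps[[i]], maps[[j]], cm, mode)$total_cost,
                     tolerance = 1e-9)
    }
  })
})

test_that("the text rendering shows columns, gaps and duplication arcs", {
  cm <- default_cost_model(c("a", "b"))
  id <- align_pair(mini_map("m1", "ab"), mini_map("m2", "ab"), cm)
  txt <- render_alignment(id)
  expect_length(grep("^arc", txt), 0)
  expect_match(txt[2], "a b$")
  expect_match(txt[3], "a b$")
  dup <- align_pair(mini_map("m1", "ab"), mini_map("m2", "abb"), cm)
  txt <- render_alignment(dup)
  expect_true(any(grepl("^arc B:1 -> B:\\[2,3\\)$", txt)))
  expect_match(txt[2], "-")  # gap opposite the duplicated unit
})
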