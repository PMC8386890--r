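test_that("all comparison metrics score identical covers as exactly 1", {
  set.seed(41)
  for (rep in 1:10) {
    uni <- sprintf("u%02d", 1:sample(4:8, 1))
    cv <- random_cover(uni, sample(1:3, 1))
    expect_identical(onmi(cv, cv, uni, variant = "lfk"), 1)
    expect_identical(onmi(cv, cv, uni, variant = "max"), 1)
    expect_identical(omega_index(cv, cv, uni), 1)
    expect_identical(f1_best_match(cv, cv), 1)
  }
})

test_that("metrics are symmetric and invariant to community order and relabeling", {
  set.seed(42)
  uni <- sprintf("u%02d", 1:7)
  for (rep in 1:10) {
    a <- random_cover(uni, 2)
    b <- random_cover(uni, 3)
    expect_equal(onmi(a, b, uni), onmi(b, a, uni))
    expect_equal(onmi(a, b, uni, variant = "max"), onmi(b, a, uni, variant = "max"))
    expect_equal(omega_index(a, b, uni), omega_index(b, a, uni))
    expect_equal(f1_best_match(a, b), f1_best_match(b, a))

    perm <- lpam_cover(sample(a$communities))
    expect_equal(onmi(perm, b, uni), onmi(a, b, uni))

    # consistent node renaming leaves every score unchanged
    ren <- setNames(sprintf("w%02d", seq_along(uni)), uni)
    a2 <- lpam_cover(lapply(a$communities, function(x) unname(ren[x])))
    b2 <- lpam_cover(lapply(b$communities, function(x) unname(ren[x])))
    expect_equal(onmi(a2, b2, unname(ren[uni])), onmi(a, b, uni))
    expect_equal(omega_index(a2, b2, unname(ren[uni])), omega_index(a, b, uni))
    expect_equal(f1_best_match(a2, b2), f1_best_match(a, b))
  }
})

test_that("hand-built examples match the frozen oracle values", {
  uni6 <- as.character(1:6)
  a <- lpam_cover(list(c("1", "2", "3"), c("4", "5", "6")))
  b <- lpam_cover(list(uni6))
  expect_equal(onmi(a, b, uni6), onmi_lfk_oracle(a, b, uni6))

  # omega on crossing pair covers: obs 1/3, exp 5/9 -> -0.5
  a4 <- lpam_cover(list(c("1", "2"), c("3", "4")))
  b4 <- lpam_cover(list(c("1", "3"), c("2", "4")))
  expect_equal(omega_index(a4, b4, as.character(1:4)), -0.5)

  # F1 of a nested pair: 2 * (1 * 0.5) / 1.5
  expect_equal(f1_best_match(lpam_cover(list(as.character(1:4))),
                             lpam_cover(list(c("1", "2")))), 2 / 3)
})

test_that("metrics match literal-formula oracles across enumerated small covers", {
  # all covers with <= 2 communities over a 3-node universe, exhaustively
  uni <- c("a", "b", "c")
  subsets <- unlist(lapply(1:3, function(s) combn(uni, s, simplify = FALSE)),
                    recursive = FALSE)
  covers <- c(lapply(subsets, function(s) lpam_cover(list(s))),
              combn(length(subsets), 2, function(ix)
                lpam_cover(subsets[ix]), simplify = FALSE))
  idx <- expand.grid(i = seq_along(covers), j = seq_along(covers))
  for (r in seq_len(nrow(idx))) {
    a <- covers[[idx$i[r]]]; b <- covers[[idx$j[r]]]
    expect_equal(onmi(a, b, uni), onmi_lfk_oracle(a, b, uni), tolerance = 1e-12)
    expect_equal(omega_index(a, b, uni), omega_oracle(a, b, uni), tolerance = 1e-12)
    expect_equal(f1_best_match(a, b), f1_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("metrics match oracles on random 5-node covers and stay in range", {
  set.seed(43)
  uni <- sprintf("n%d", 1:5)
  for (rep in 1:40) {
    a <- random_cover(uni, sample(1:3, 1))
    b <- random_cover(uni, sample(1:3, 1))
    o <- onmi(a, b, uni)
    expect_equal(o, onmi_lfk_oracle(a, b, uni), tolerance = 1e-12)
    expect_gte(o, 0); expect_lte(o, 1)
    om <- omega_index(a, b, uni)
    expect_equal(om, omega_oracle(a, b, uni), tolerance = 1e-12)
    expect_lte(om, 1)
    f <- f1_best_match(a, b)
    expect_equal(f, f1_oracle(a, b), tolerance = 1e-12)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_gte(onmi(a, b, uni, variant = "max"), 0)
    expect_lte(onmi(a, b, uni, variant = "max"), 1)
  }
})

test_that("cover_stats reproduces the lattice quadrant statistics", {
  g <- grid_graph(8, 8)
  rows <- as.integer(sub("r(\\d)c\\d", "\\1", g$nodes))
  cols <- as.integer(sub("r\\dc(\\d)", "\\1", g$nodes))
  quads <- split(g$nodes, paste(rows > 4, cols > 4))
  st <- cover_stats(g, quads)
  expect_equal(st$avg_internal_degree, 3)             # 2 * 24 / 16
  expect_equal(st$normalized_cut, 8 / 56 + 8 / 168)   # = 0.190476...
  expect_equal(round(st$normalized_cut, 2), 0.19)

  whole <- cover_stats(g, list(g$nodes))
  expect_equal(whole$avg_internal_degree, 2 * 112 / 64)
  expect_equal(whole$normalized_cut, 0)
  expect_message(cover_stats(g, list(g$nodes, character())), "empty")
  expect_error(cover_stats(g, list(c("zz"))), "not in graph")
})

test_that("universe handling rejects foreign members and empty universes", {
  a <- lpam_cover(list(c("a", "b")))
  expect_error(onmi(a, a, universe = character()), "empty")
  expect_error(onmi(a, a, universe = c("a")), "outside the universe")
  expect_no_error(omega_index(a, a, universe = c("a", "b")))
  expect_error(omega_index(lpam_cover(list("a")), lpam_cover(list("a")),
                           universe = "a"), "at least 2")
})
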