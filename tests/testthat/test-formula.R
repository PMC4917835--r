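test_that("formula parsing handles counts, implicit ones, and repeats", {
  expect_equal(unclass(parse_formula("C6H6")), c(C = 6L, H = 6L),
               ignore_attr = TRUE)
  expect_equal(names(parse_formula("C6H6")), c("C", "H"))
  expect_equal(unclass(parse_formula("C18H18")), c(C = 18L, H = 18L),
               ignore_attr = TRUE)
  expect_equal(sum(parse_formula("C")), 1L)
  # Hill ordering and repeated tokens
  f <- parse_formula("O2C3H8C1")
  expect_equal(names(f), c("C", "H", "O"))
  expect_equal(as.integer(f), c(4L, 8L, 2L))
})

test_that("formula parsing rejects malformed input naming the offender", {
  expect_error(parse_formula("C6H5Cl2X"), "X")
  expect_error(parse_formula("C0H4"), "zero")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C6(H6)"), "grammar")
})

test_that("parse/format round-trips over random formulas", {
  set.seed(42)
  els <- allowed_elements()
  for (i in 1:50) {
    k <- sample(1:6, 1)
    f <- setNames(sample(1:40, k), sample(els, k))
    txt <- format_formula(f)
    expect_equal(unclass(parse_formula(txt)),
                 f[names(parse_formula(txt))], ignore_attr = TRUE)
  }
})

test_that("molecular weights match hand sums in both mass modes", {
  bz <- parse_formula("C6H6")
  expect_identical(molecular_weight(bz, "nominal"), 78)
  expect_identical(molecular_weight(parse_formula("C18H18"), "nominal"), 234)
  expect_equal(molecular_weight(bz, "average"), 78.114, tolerance = 1e-12)
  # C9H13N3O: 9*12 + 13*1 + 3*14 + 16 = 179
  expect_identical(molecular_weight(parse_formula("C9H13N3O"), "nominal"),
                   179)
  expect_error(molecular_weight(c(Na = 1L), "average"), "missing")
})

test_that("atom counts decompose into C, H and heteroatoms", {
  ac <- atom_counts(parse_formula("C9H13N3O"))
  expect_equal(ac[c("ac_total", "ac_c", "ac_h", "ac_hetero")],
               list(ac_total = 26L, ac_c = 9L, ac_h = 13L, ac_hetero = 4L))
  expect_equal(sum(ac$per_element), ac$ac_total)
  expect_equal(atom_counts(parse_formula("C6H6"))$ac_hetero, 0L)
  expect_equal(atom_counts(parse_formula("Cl2"))[1:4],
               list(ac_total = 2L, ac_c = 0L, ac_h = 0L, ac_hetero = 2L))
})

test_that("nitrogen parity classifies CHNO and non-CHNO records", {
  expect_equal(nitrogen_parity(179, 3, TRUE), "consistent")
  expect_equal(nitrogen_parity(78, 0, TRUE), "consistent")
  expect_equal(nitrogen_parity(180, 3, TRUE), "inconsistent")
  expect_equal(nitrogen_parity(200, 2, FALSE), "not_applicable")
})

test_that("nitrogen rule holds exhaustively over a CHNO composition grid", {
  # every valence-feasible C/H/N/O composition must pair MW parity with
  # N parity; infeasible compositions (negative or fractional DBE) are
  # excluded by construction
  grid <- expand.grid(C = 1:20, H = 0:40, N = 0:6, O = 0:6)
  dbe2 <- with(grid, 2 * C + 2 + N - H)
  feasible <- dbe2 >= 0 & dbe2 %% 2 == 0
  g <- grid[feasible, ]
  mw_nominal <- with(g, 12 * C + H + 14 * N + 16 * O)
  expect_true(all(mw_nominal %% 2 == g$N %% 2))
  expect_gt(nrow(g), 10000)
})

test_that("average-vs-nominal MW difference is bounded per atom", {
  tab <- mass_table()
  max_diff <- max(abs(tab$average - tab$nominal))
  expect_lte(max_diff, 1.1)  # selenium: 78.971 vs 80
  set.seed(7)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    f <- setNames(sample(1:30, k), sample(allowed_elements(), k))
    d <- abs(molecular_weight(f, "average") - molecular_weight(f, "nominal"))
    expect_lte(d, sum(f) * max_diff)
  }
})

test_that("descriptor table reproduces scalar descriptors at scale", {
  cat <- data.frame(record_id = c("a", "b", "c"),
                    formula = c("C6H6", "C9H13N3O", "C6H5Cl"),
                    price_wbm = c(10, 20, 30))
  d <- compute_descriptors(cat)
  expect_equal(d$mw_nominal, c(78L, 179L, 112L))
  expect_equal(d$ac_total, c(12L, 26L, 12L))
  expect_equal(d$chno_only, c(TRUE, TRUE, FALSE))
  expect_equal(d$mw_parity, c("even", "odd", "even"))
  expect_equal(d$n_parity, c("even", "odd", "even"))
  expect_equal(d$p2_mbm, d$price_wbm * d$mw_avg)
  # parity consistency flag via nitrogen_parity
  np <- nitrogen_parity(d$mw_nominal, d$cnt_N, d$chno_only)
  expect_equal(np, c("consistent", "consistent", "not_applicable"))
})

test_that("vectorised tokeniser agrees with the scalar parser", {
  forms <- c("C6H6", "C9H13N3O", "C2H3BrClNO2S", "CH4", "C22H30N4O2Se")
  counts <- qser:::parse_formula_counts(forms)
  expect_true(all(attr(counts, "valid")))
  for (i in seq_along(forms)) {
    f <- parse_formula(forms[i])
    expect_equal(counts[i, names(f)], unclass(f), ignore_attr = TRUE,
                 label = forms[i])
    expect_equal(sum(counts[i, setdiff(colnames(counts), names(f))]), 0L)
  }
  bad <- qser:::parse_formula_counts(c("C6H6", "C6H5X2", ""))
  expect_equal(attr(bad, "valid"), c(TRUE, FALSE, FALSE))
})
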