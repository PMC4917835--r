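test_that("implicit hydrogens follow the valence model", {
  # benzene drawn with alternating single/double bonds, no explicit H
  expect_equal(format_formula(formula_from_ctab(benzene_ctab())), "C6H6")
  # methane: single unbonded carbon
  methane <- v2000_block("methane", list("C"))
  expect_equal(format_formula(formula_from_ctab(methane)), "CH4")
  # pyridine-like: N in an aromatic-order ring gets no H
  pyr <- v2000_block("pyridine", as.list(c(rep("C", 5), "N")),
                     bonds = cbind(1:6, c(2:6, 1), rep(4, 6)))
  expect_equal(format_formula(formula_from_ctab(pyr)), "C5H5N")
  # sulfur expands valence: degree 3 -> lowest feasible state 4
  so <- v2000_block("sulfoxide-ish", list("S", "O", "C", "C"),
                    bonds = cbind(c(1, 1, 1), c(2, 3, 4), c(2, 1, 1)))
  f <- formula_from_ctab(so)
  expect_equal(unclass(f)[c("C", "S", "O")], c(C = 2L, S = 1L, O = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(f)[["H"]], 6L)  # 2x CH3, none on S (4-2-2=0)
})

test_that("explicit-hydrogen tables gain no extra hydrogens", {
  # methane with all four H explicit
  m <- v2000_block("methane-explicit", list("C", "H", "H", "H", "H"),
                   bonds = cbind(rep(1, 4), 2:5, rep(1, 4)))
  expect_equal(format_formula(formula_from_ctab(m)), "CH4")
})

test_that("charges adjust the implicit hydrogen count", {
  # legacy charge column: code 3 is +1; N+ with one bond -> NH3+ style
  nplus <- v2000_block("ammonium-ish", list("N", "C"),
                       bonds = cbind(1, 2, 1))
  base <- formula_from_ctab(nplus)
  expect_equal(unclass(base)[["H"]], 5L)  # CH3-NH2
  charged <- v2000_block("ammonium-ish", list("N", "C"),
                         bonds = cbind(1, 2, 1))
  charged[5] <- v2000_atom("N", 3L)  # legacy code 3 = +1
  expect_equal(unclass(formula_from_ctab(charged))[["H"]], 4L)
  # M CHG property line supersedes the atom block
  mchg <- v2000_block("ammonium-chg", list("N", "C"),
                      bonds = cbind(1, 2, 1),
                      extra = "M  CHG  1   1   1")
  expect_equal(unclass(formula_from_ctab(mchg))[["H"]], 4L)
})

test_that("malformed connection tables are rejected informatively", {
  blk <- v2000_block("xx", list("Xx"))
  expect_error(formula_from_ctab(blk), "Xx")
  bad <- benzene_ctab()
  bad[4] <- "  a  b  0  0  0  0  0  0  0  0999 V2000"
  expect_error(formula_from_ctab(bad), "line 4")
  v3 <- benzene_ctab()
  v3[4] <- "  0  0  0     0  0            999 V3000"
  expect_error(formula_from_ctab(v3), "V3000")
  # over-valent carbon is flagged, not silently accepted
  penta <- v2000_block("penta-C", as.list(rep("C", 6)),
                       bonds = cbind(rep(1, 5), 2:6, rep(1, 5)))
  expect_error(formula_from_ctab(penta), "valence")
})

test_that("ctab formulas agree with an independent cheminformatics toolkit", {
  skip_if_not_installed("ChemmineR")
  ethane <- v2000_block("ethane", list("C", "C"), bonds = cbind(1, 2, 1))
  pyridine <- v2000_block("pyridine", as.list(c(rep("C", 5), "N")),
                          bonds = cbind(1:6, c(2:6, 1),
                                        c(2, 1, 2, 1, 2, 1)))
  path <- tempfile(fileext = ".sdf")
  write_sdf_fixture(list(benzene_ctab(), ethane, pyridine), path)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ours <- vapply(list(benzene_ctab(), ethane, pyridine),
                 function(b) format_formula(formula_from_ctab(b)),
                 character(1))
  theirs <- unname(ChemmineR::MF(sdf, addH = TRUE))
  expect_equal(ours, theirs)
})

test_that("SD-file curation keeps, drops and counts records correctly", {
  path <- tempfile(fileext = ".sdf")
  recs <- list(
    with_items(benzene_ctab(), PRICE = "10.5", SAS = "3.2"),
    # duplicate of the first (same formula, same price, other id)
    with_items({ b <- benzene_ctab(); b[1] <- "benzene-copy"; b },
               PRICE = "10.5"),
    # kept via MF despite empty ctab
    with_items(c("mf-only", "", "",
                 "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END"),
               MF = "C6H5Cl", PRICE = "4.0"),
    # zero price -> dropped
    with_items({ b <- benzene_ctab(); b[1] <- "freebie"; b },
               PRICE = "0"),
    # broken structure, no MF -> dropped
    with_items(c("broken", "", "",
                 "  2  0  0  0  0  0  0  0  0  0999 V2000",
                 v2000_atom("C"), v2000_atom("Zz"), "M  END"),
               PRICE = "7.0"))
  write_sdf_fixture(recs, path)
  res <- suppressMessages(read_catalog_sdf(path))
  expect_equal(res$report$n_input, 5L)
  expect_equal(res$report$n_kept, 2L)
  expect_equal(res$report$n_dropped_duplicates, 1L)
  expect_equal(res$report$n_dropped_missing_price, 1L)
  expect_equal(res$report$n_dropped_invalid_structure, 1L)
  expect_equal(res$catalog$formula, c("C6H6", "C6H5Cl"))
  expect_equal(res$catalog$price_wbm, c(10.5, 4.0))
  expect_equal(res$catalog$sas[1], 3.2)
})

test_that("catalogue SDF writer round-trips through the reader", {
  cat0 <- data.table::data.table(
    record_id = c("a", "b"), formula = c("C6H6", "C9H13N3O"),
    price_wbm = c(12.25, 530), sas = c(2.5, NA))
  path <- tempfile(fileext = ".sdf")
  write_catalog_sdf(cat0, path)
  back <- read_catalog_sdf(path)
  expect_equal(back$catalog$formula, cat0$formula)
  expect_equal(back$catalog$price_wbm, cat0$price_wbm)
  expect_equal(back$catalog$sas, cat0$sas)
  expect_equal(back$report$n_kept, 2L)
})
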