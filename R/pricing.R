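# Weight-based vs molar-based price metrics. The market quotes prices
# per weight unit ($/g, WBM); chemistry counts molecules, so the molar
# price ($/mol, MBM) is the WBM price scaled by the molar mass: one mole
# of a 78 Da compound weighs 78 g, one mole of a 234 Da compound three
# times as much.

#' Convert a weight-based price to a molar price
#'
#' @param p1 Price in $/g (positive).
#' @param mw Average molecular weight in Da, i.e. molar mass in g/mol.
#' @return Price in $/mol: `p1 * mw`.
#' @export
#' @examples
#' wbm_to_mbm(1, 78)   # a mole of benzene at 1 $/g costs 78 $
#' wbm_to_mbm(1, 234)  # a mole of [18]annulene at 1 $/g costs 234 $
wbm_to_mbm <- function(p1, mw) {
  check_positive(p1, "p1"); check_positive(mw, "mw")
  p1 * mw
}

#' Convert a molar price back to a weight-based price
#'
#' Exact inverse of [wbm_to_mbm()].
#'
#' @param p2 Price in $/mol (positive).
#' @param mw Average molecular weight in Da.
#' @return Price in $/g: `p2 / mw`.
#' @export
mbm_to_wbm <- function(p2, mw) {
  check_positive(p2, "p2"); check_positive(mw, "mw")
  p2 / mw
}

#' Molecule-count ratio at equal weight
#'
#' How many molecules of compound A fit in the weight of one molecule of
#' compound B: `mw_b / mw_a`. Benzene (78 Da) against [18]annulene
#' (234 Da) gives 3 — an equal weight holds three times as many benzene
#' molecules.
#'
#' @param mw_a,mw_b Molecular weights in Da (positive).
#' @return Dimensionless ratio.
#' @export
#' @examples
#' molecules_per_gram_ratio(78, 234)  # 3
molecules_per_gram_ratio <- function(mw_a, mw_b) {
  check_positive(mw_a, "mw_a"); check_positive(mw_b, "mw_b")
  mw_b / mw_a
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'", name, "' must be positive and finite")
  invisible(x)
}
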