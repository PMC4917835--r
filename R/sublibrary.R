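# Heteroatom sub-libraries and the nominal-mass parity analysis. Within
# a C/H/N/O-only nitrogen sub-library, the nitrogen rule splits every
# iso-MW bin into an even-MW (even N) and an odd-MW (odd N) class; the
# comparison of their mean prices, together with their mean N counts,
# probes whether the atom count drives pricing inside mass-equivalent
# compound classes.

#' Sub-library specification
#'
#' @param element Element symbol the sub-library selects on.
#' @param min_count Minimum per-molecule count of that element (>= 1).
#' @param chno_only Restrict to C/H/N/O-only compositions (required for
#'   nitrogen-rule parity arguments to hold).
#' @return A `qser_sublibrary_spec` list.
#' @export
sublibrary_spec <- function(element, min_count = 1L, chno_only = FALSE) {
  if (!element %in% allowed_elements())
    stop("unknown element: ", element)
  stopifnot(min_count >= 1L)
  structure(list(element = element, min_count = as.integer(min_count),
                 chno_only = isTRUE(chno_only)),
            class = "qser_sublibrary_spec")
}

#' Extract a heteroatom sub-library
#'
#' Filters a descriptor table to records containing at least
#' `min_count` atoms of the spec's element, optionally restricted to
#' C/H/N/O-only compositions. A pure filter: record order is preserved
#' and re-applying the same spec is a no-op.
#'
#' @param descriptors A [compute_descriptors()] table.
#' @param spec A [sublibrary_spec()].
#' @return The filtered descriptor table (possibly empty, with a
#'   warning).
#' @export
extract_sublibrary <- function(descriptors, spec) {
  stopifnot(inherits(spec, "qser_sublibrary_spec"))
  dt <- data.table::as.data.table(descriptors)
  cnt_col <- paste0("cnt_", spec$element)
  cnt <- if (spec$element == "C") dt$ac_c
         else if (spec$element == "H") dt$ac_h
         else dt[[cnt_col]]
  if (is.null(cnt)) stop("descriptor table lacks counts for ", spec$element)
  keep <- cnt >= spec$min_count
  if (spec$chno_only) keep <- keep & dt$chno_only
  out <- dt[keep]
  if (nrow(out) == 0L)
    warning("sub-library for ", spec$element, " >= ", spec$min_count,
            " is empty")
  out
}

#' Parity-split bin comparison
#'
#' Splits a (nitrogen) sub-library by the parity of the nominal
#' molecular weight, bins both classes on the same grid, and emits one
#' comparison row per bin occupied by both classes: per-class occupancy,
#' mean price and mean nitrogen count, plus which class carries more
#' nitrogen and which is cheaper.
#'
#' @param descriptors Sub-library descriptor table (use
#'   [extract_sublibrary()] with `chno_only = TRUE` for nitrogen-rule
#'   validity).
#' @param spec A [bin_spec()]; default 2 Da bins over `mw_avg`. At 1 Da
#'   the two parity classes occupy alternating bins (adjacent nominal
#'   masses), so a within-bin contrast needs bins at least 2 Da wide.
#' @param price_var `"price_wbm"` or `"p2_mbm"`.
#' @return `data.table` with columns `bin`, `center`, `n_even`, `n_odd`,
#'   `mean_price_even`, `mean_price_odd`, `mean_n_even`, `mean_n_odd`,
#'   `higher_n_class`, `cheaper_class`.
#' @export
parity_split_bins <- function(descriptors,
                              spec = bin_spec("mw_avg", resolution = 2),
                              price_var = c("price_wbm", "p2_mbm")) {
  price_var <- match.arg(price_var)
  dt <- data.table::as.data.table(descriptors)
  stopifnot(all(c("mw_parity", "cnt_N", price_var, spec$variable)
                %in% names(dt)))
  dt <- dt[, c(spec$variable, "mw_parity", "cnt_N", price_var),
           with = FALSE]
  data.table::setnames(dt, c(".v", ".parity", ".n_count", ".price"))
  dt[, ".bin" := assign_bin(.v, spec)]
  agg <- dt[, list(n = .N, mean_price = mean(.price),
                   mean_n = mean(as.numeric(.n_count))),
            keyby = c(".bin", ".parity")]
  wide <- data.table::dcast(agg, .bin ~ .parity,
                            value.var = c("n", "mean_price", "mean_n"))
  for (col in c("n_even", "n_odd", "mean_price_even", "mean_price_odd",
                "mean_n_even", "mean_n_odd"))
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  both <- !is.na(wide$n_even) & !is.na(wide$n_odd)
  out <- wide[both]
  data.table::setnames(out, ".bin", "bin")
  out[, "center" := spec$origin + (bin + 0.5) * spec$resolution]
  out[, "higher_n_class" := ifelse(mean_n_even > mean_n_odd, "even",
                            ifelse(mean_n_odd > mean_n_even, "odd", "tie"))]
  out[, "cheaper_class" := ifelse(mean_price_even < mean_price_odd, "even",
                           ifelse(mean_price_odd < mean_price_even, "odd",
                                  "tie"))]
  data.table::setcolorder(out, c("bin", "center", "n_even", "n_odd",
                                 "mean_price_even", "mean_price_odd",
                                 "mean_n_even", "mean_n_odd",
                                 "higher_n_class", "cheaper_class"))
  out[]
}

#' Mean price as a function of a heteroatom count
#'
#' For `k = 0, 1, 2, ...` reports the mean WBM and MBM price over the
#' records carrying exactly `k` atoms of the element, with occupancy.
#' Counts below `min_occupancy` are kept in the table but flagged as
#' unstable (`reported = FALSE`), mirroring the sparse-bin caveat.
#'
#' @param descriptors A [compute_descriptors()] table with prices.
#' @param element Element symbol.
#' @param min_occupancy Occupancy needed for a per-count mean to be
#'   flagged reliable (default 30).
#' @return `data.table` with `count`, `n`, `mean_p1`, `mean_p2`,
#'   `reported`.
#' @export
heteroatom_price_profile <- function(descriptors, element,
                                     min_occupancy = 30L) {
  dt <- data.table::as.data.table(descriptors)
  cnt <- if (element == "C") dt$ac_c
         else if (element == "H") dt$ac_h
         else dt[[paste0("cnt_", element)]]
  if (is.null(cnt)) stop("descriptor table lacks counts for ", element)
  work <- data.table::data.table(count = cnt, p1 = dt$price_wbm,
                                 p2 = dt$p2_mbm)
  prof <- work[, list(n = .N, mean_p1 = mean(p1), mean_p2 = mean(p2)),
               keyby = "count"]
  prof[, "reported" := n >= min_occupancy]
  prof[]
}
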