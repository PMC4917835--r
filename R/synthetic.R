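# Synthetic commercial-catalogue generator. Emulates the statistical
# structure of a 2.2M-compound building-block catalogue: a truncated
# Gaussian-mixture MW distribution on 218.26-738.74 Da calibrated so
# ~96% of records sit below 350 Da and ~99% below 400 Da with the
# global mode near 250 Da; valence-feasible molecular formulas matched
# to the sampled MW; a piecewise-linear structural price model with
# per-element premiums/discounts calibrated to a 537.83 $/g library
# mean; and a synthetic-accessibility stand-in column (an affine
# function of the atom count plus noise on a 1-10 scale, tuned to
# corr(SAS, AC) ~ 0.38). The SAS column imitates only that marginal
# relationship; it carries no fidelity to any real accessibility
# algorithm.

#' Generator configuration
#'
#' Defaults define the reference study conditions; every component can
#' be overridden for experiments.
#'
#' @param n Library size.
#' @param seed Integer RNG seed; the whole catalogue is a deterministic
#'   function of (config, seed).
#' @param mw_range Truncation support in Da.
#' @param mw_mixture List with `weights`, `means`, `sds` of the
#'   truncated Gaussian mixture.
#' @param price_model List: `mw_slope_low` ($/g per Da below the
#'   breakpoint), `breakpoint` (Da; the MW-price trend holds only in the
#'   low-MW range, flat above), `premiums` (named $/g contribution per
#'   atom; N positive, heavy halogens negative), `noise_sd` ($/g),
#'   `floor_price` ($/g) and `target_mean_price` ($/g) hit by solving
#'   for the intercept.
#' @param sas_model List: `center`, `signal_sd` (scale of the atom-count
#'   signal on the score axis), `target_cor_ac` and `range` for
#'   clipping.
#' @param element_probs Named list of `c(prob, max_count)` per optional
#'   heteroatom: inclusion probability and the maximum count drawn
#'   (counts uniform on `1:max_count`).
#' @param hc_ratio_range Per-molecule H:C ratio range for formula
#'   synthesis.
#' @return A `qser_generator_config` list.
#' @export
generator_config <- function(
    n = 100000L, seed = 20260101L,
    mw_range = c(218.26, 738.74),
    mw_mixture = list(weights = c(0.600, 0.388, 0.012),
                      means = c(250, 300, 480),
                      sds = c(24, 34, 110)),
    price_model = list(mw_slope_low = 2.0, breakpoint = 250,
                       premiums = c(N = 15, O = 5, S = 5, F = 5,
                                    Cl = -20, Br = -25, I = -30,
                                    Se = -25),
                       noise_sd = 150, floor_price = 1,
                       target_mean_price = 537.83),
    sas_model = list(center = 5.5, signal_sd = 0.5,
                     target_cor_ac = 0.380, range = c(1, 10)),
    element_probs = list(N = c(0.60, 4), O = c(0.50, 3), S = c(0.12, 1),
                         F = c(0.10, 3), Cl = c(0.12, 2), Br = c(0.05, 1),
                         I = c(0.02, 1), Se = c(0.015, 1)),
    hc_ratio_range = c(0.9, 1.7)) {
  stopifnot(abs(sum(mw_mixture$weights) - 1) < 1e-8,
            all(mw_mixture$sds > 0), n >= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 mw_range = mw_range, mw_mixture = mw_mixture,
                 price_model = price_model, sas_model = sas_model,
                 element_probs = element_probs,
                 hc_ratio_range = hc_ratio_range),
            class = "qser_generator_config")
}

# inverse-CDF sampling from the truncated mixture, using the ambient
# RNG stream (callers own the seed)
.sample_mw_stream <- function(count, config) {
  mix <- config$mw_mixture
  lo <- config$mw_range[1]; hi <- config$mw_range[2]
  comp <- sample.int(length(mix$weights), count, replace = TRUE,
                     prob = mix$weights)
  u <- stats::runif(count)
  m <- mix$means[comp]; s <- mix$sds[comp]
  plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
  stats::qnorm(plo + u * (phi - plo), m, s)
}

#' Sample molecular weights from the calibrated distribution
#'
#' @param count Number of draws.
#' @param config A [generator_config()].
#' @param seed RNG seed.
#' @return Numeric vector of MW values inside the configured range.
#' @export
#' @examples
#' mw <- sample_mw(10000, seed = 7)
#' mean(mw < 350)  # ~0.96
sample_mw <- function(count, config = generator_config(), seed = 1L) {
  set.seed(seed)
  .sample_mw_stream(count, config)
}

# Vectorised formula synthesis: draw heteroatom counts, then solve
# integer C/H counts so that (i) the average mass matches the target
# within 0.5 Da and (ii) the degree of unsaturation
# DBE = (2C + 2 + N - H - halogens)/2 is a non-negative integer.
# Since 2C + 2 is even, (ii)'s integrality fixes the parity of H to
# that of N + halogens; with parity fixed, H moves in steps of 2 and C
# in steps of 1, and scanning C over a small window always brings the
# mass residual under half a hydrogen.
.synthesize_formulas <- function(mw, config, max_rounds = 12L) {
  n <- length(mw)
  tab <- mass_table()$average
  hets <- names(config$element_probs)
  counts <- matrix(0L, n, length(hets) + 2L,
                   dimnames = list(NULL, c("C", "H", hets)))
  todo <- rep(TRUE, n)
  for (round in seq_len(max_rounds)) {
    idx <- which(todo)
    if (!length(idx)) break
    k <- length(idx)
    het <- matrix(0L, k, length(hets), dimnames = list(NULL, hets))
    for (e in hets) {
      p <- config$element_probs[[e]]
      inc <- stats::runif(k) < p[1]
      cnt <- if (p[2] > 1) sample.int(p[2], k, replace = TRUE) else rep(1L, k)
      het[, e] <- ifelse(inc, cnt, 0L)
    }
    het_mass <- as.vector(het %*% tab[hets])
    # keep enough mass for a carbon skeleton: shed halogens/S/Se first
    thin <- mw[idx] - het_mass < 60
    if (any(thin)) {
      het[thin, setdiff(hets, c("N", "O"))] <- 0L
      het_mass <- as.vector(het %*% tab[hets])
    }
    hal <- rowSums(het[, intersect(.HALOGENS, hets), drop = FALSE])
    ratio <- stats::runif(k, config$hc_ratio_range[1],
                          config$hc_ratio_range[2])
    best_err <- rep(Inf, k)
    best_c <- rep(NA_integer_, k); best_h <- rep(NA_integer_, k)
    best_extra_n <- rep(0L, k)
    # Some fractional target masses only admit solutions in one H-parity
    # class; since DBE integrality ties H's parity to N + halogens, try
    # the draw as-is and with one extra N (which flips the parity).
    for (extra_n in 0:1) {
      m <- mw[idx] - het_mass - extra_n * tab[["N"]]
      parity <- (het[, "N"] + extra_n + hal) %% 2L
      c0 <- round(m / (tab[["C"]] + tab[["H"]] * ratio))
      # With parity fixed, the residual at the best H moves by only
      # ~0.085 Da per extra carbon (12 * 1.008 vs 12.011): scan a wide
      # carbon window, since DBE >= 0 blocks the short direction.
      for (d in -7:26) {
        cc <- c0 + d
        hraw <- (m - tab[["C"]] * cc) / tab[["H"]]
        hh <- 2 * round((hraw - parity) / 2) + parity
        err <- abs(tab[["C"]] * cc + tab[["H"]] * hh - m)
        dbe2 <- 2 * cc + 2 + het[, "N"] + extra_n - hh - hal
        ok <- cc >= 1 & hh >= 0 & dbe2 >= 0 & err < best_err
        best_err[ok] <- err[ok]
        best_c[ok] <- as.integer(cc[ok]); best_h[ok] <- as.integer(hh[ok])
        best_extra_n[ok] <- extra_n
      }
    }
    done <- !is.na(best_c) & best_err <= 0.5
    if (any(done)) {
      rows <- idx[done]
      counts[rows, "C"] <- best_c[done]
      counts[rows, "H"] <- best_h[done]
      counts[rows, hets] <- het[done, , drop = FALSE]
      counts[rows, "N"] <- counts[rows, "N"] + best_extra_n[done]
      todo[rows] <- FALSE
    }
  }
  if (any(todo))
    stop(sum(todo), " target MW value(s) admit no valence-feasible ",
         "formula after ", max_rounds, " rounds")
  counts
}

#' Synthesize one valence-feasible formula near a target MW
#'
#' @param target_mw Target average molecular weight (Da), inside the
#'   configured range.
#' @param config A [generator_config()].
#' @param seed RNG seed.
#' @return A `molecular_formula` whose average MW is within 0.5 Da of
#'   the target and whose degree of unsaturation is a non-negative
#'   integer.
#' @export
#' @examples
#' format_formula(formula_for_mw(250.3, seed = 1))
formula_for_mw <- function(target_mw, config = generator_config(),
                           seed = 1L) {
  if (target_mw < config$mw_range[1] - 0.5 ||
      target_mw > config$mw_range[2] + 0.5)
    stop("target MW outside the configured range")
  set.seed(seed)
  counts <- .synthesize_formulas(target_mw, config)[1L, ]
  counts <- counts[counts > 0L]
  ord <- hill_order(names(counts))
  structure(as.integer(counts[ord]), names = ord,
            class = "molecular_formula")
}

# structural (noise-free, intercept-free) price component
.structural_price <- function(counts, mw, pm) {
  prem <- pm$premiums
  contrib <- as.vector(counts[, names(prem), drop = FALSE] %*% prem)
  pm$mw_slope_low * pmin(mw, pm$breakpoint) + contrib
}

#' Structural price of a single formula
#'
#' The generator's noise-free price model for one molecule: a linear MW
#' term saturating at the breakpoint, plus the per-atom element
#' premiums, plus the supplied intercept and noise draw, floored at the
#' configured positive minimum. Adding one Cl atom to a formula changes
#' the zero-noise price by exactly `premiums["Cl"]`.
#'
#' @param formula A `molecular_formula` count vector.
#' @param config A [generator_config()].
#' @param intercept Price intercept in $/g (the catalogue-level
#'   calibration solves for this; 0 by default).
#' @param noise A realized noise draw in $/g (0 for the deterministic
#'   part).
#' @return Price in $/g.
#' @export
price_for_record <- function(formula, config = generator_config(),
                             intercept = 0, noise = 0) {
  pm <- config$price_model
  counts <- unclass(formula)
  mw <- molecular_weight(formula, "average")
  prem <- pm$premiums
  contrib <- sum(prem[names(counts)[names(counts) %in% names(prem)]] *
                   counts[names(counts) %in% names(prem)])
  max(pm$floor_price,
      pm$mw_slope_low * min(mw, pm$breakpoint) + contrib + intercept +
        noise)
}

#' Synthetic-accessibility stand-in score of a single formula
#'
#' Affine in the total atom count on a standardized scale, clipped to
#' the score range. `ac_center`/`ac_scale` standardize the atom count
#' against the library the record belongs to.
#'
#' @inheritParams price_for_record
#' @param ac_center,ac_scale Library mean and SD of the total atom
#'   count.
#' @param noise A realized noise draw on the score axis.
#' @return Score clipped to the configured range (default 1-10).
#' @export
sas_for_record <- function(formula, config = generator_config(),
                           ac_center = 40, ac_scale = 10, noise = 0) {
  sm <- config$sas_model
  ac <- sum(unclass(formula))
  raw <- sm$center + sm$signal_sd * (ac - ac_center) / ac_scale + noise
  min(sm$range[2], max(sm$range[1], raw))
}

#' Generate a synthetic commercial catalogue
#'
#' Fully seed-deterministic: MW values are sampled from the calibrated
#' mixture, formulas synthesized to match them, prices drawn from the
#' structural model (intercept solved so the expected library mean hits
#' the target), and SAS scores from the atom-count model. The planted
#' ground truth (realized intercept, per-record structural price, SAS
#' noise SD) is returned alongside for parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return List of class `qser_synthetic_catalog`: `catalog` (a
#'   `data.table`: `record_id`, `formula`, `price_wbm`, `sas`),
#'   `ground_truth` (list: `config`, `intercept`, `structural_price`,
#'   `mw`, `mw_target`, `sas_noise_sd`).
#' @export
#' @examples
#' g <- generate_catalog(generator_config(n = 100, seed = 42))
#' head(g$catalog)
generate_catalog <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n
  mw_target <- .sample_mw_stream(n, config)
  counts <- .synthesize_formulas(mw_target, config)
  tab <- mass_table()$average
  mw <- as.vector(counts %*% tab[colnames(counts)])
  pm <- config$price_model
  struct <- .structural_price(counts, mw, pm)
  intercept <- pm$target_mean_price - mean(struct)
  price <- pmax(pm$floor_price,
                struct + intercept + stats::rnorm(n, 0, pm$noise_sd))
  sm <- config$sas_model
  ac <- rowSums(counts)
  z <- (ac - mean(ac)) / stats::sd(ac)
  r <- sm$target_cor_ac
  noise_sd <- sm$signal_sd * sqrt(1 / r^2 - 1)
  sas <- pmin(sm$range[2],
              pmax(sm$range[1],
                   sm$center + sm$signal_sd * z +
                     stats::rnorm(n, 0, noise_sd)))
  formulas <- .format_formula_matrix(counts)
  catalog <- data.table::data.table(
    record_id = sprintf("SYN%07d", seq_len(n)),
    formula = formulas, price_wbm = price, sas = sas)
  structure(list(catalog = catalog,
                 ground_truth = list(config = config,
                                     intercept = intercept,
                                     structural_price = struct,
                                     mw = mw, mw_target = mw_target,
                                     sas_noise_sd = noise_sd)),
            class = "qser_synthetic_catalog")
}

#' @export
print.qser_synthetic_catalog <- function(x, ...) {
  cat("<synthetic catalogue> n =", nrow(x$catalog),
      "seed =", x$ground_truth$config$seed, "\n")
  invisible(x)
}

# vectorised Hill-notation strings from a count matrix
.format_formula_matrix <- function(counts) {
  ord <- hill_order(colnames(counts))
  parts <- lapply(ord, function(e) {
    k <- counts[, e]
    ifelse(k == 0L, "", ifelse(k == 1L, e, paste0(e, k)))
  })
  do.call(paste0, parts)
}
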