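# Independent oracles and fixture builders shared across the suite.

# Brute-force group-by: per-bin counts and means computed with tapply,
# independently of the data.table path used by build_bin_table().
oracle_bin_table <- function(values, spec, tracked) {
  idx <- as.integer(floor((values[[spec$variable]] - spec$origin) /
                            spec$resolution))
  lev <- sort(unique(idx))
  f <- factor(idx, levels = lev)
  out <- data.frame(bin = lev, n = as.integer(table(f)))
  for (v in tracked)
    out[[paste0("mean_", v)]] <-
      as.numeric(tapply(as.numeric(values[[v]]), f, mean))
  out
}

# Small deterministic random catalogue of raw records (no generator
# involvement) for binning/correlation unit tests.
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    mw_avg = runif(n, 100, 500),
    price_wbm = rlnorm(n, 5, 1),
    ac_total = sample(10:80, n, replace = TRUE),
    sas = runif(n, 1, 10))
}

# Hand-built V2000 blocks (fixed-width atom lines: coords, symbol at
# cols 32-34, mass diff 35-36, charge code 37-39).
v2000_atom <- function(sym, chg_code = 0L) {
  sprintf("    0.0000    0.0000    0.0000 %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
          sym, chg_code)
}

v2000_block <- function(name, atoms, bonds = NULL, extra = character()) {
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  bond_lines <- if (nb) apply(bonds, 1, function(b)
    sprintf("%3d%3d%3d  0", b[1], b[2], b[3])) else character()
  c(name, "  qser test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(atoms), nb),
    vapply(atoms, v2000_atom, character(1)),
    bond_lines, extra, "M  END")
}

benzene_ctab <- function() {
  v2000_block("benzene", as.list(rep("C", 6)),
              bonds = cbind(1:6, c(2:6, 1), c(2, 1, 2, 1, 2, 1)))
}

write_sdf_fixture <- function(records, path) {
  blocks <- unlist(lapply(records, function(r) c(r, "$$$$")))
  writeLines(blocks, path)
  path
}

# SD-file record: ctab lines plus data items
with_items <- function(block, ...) {
  items <- list(...)
  for (nm in names(items))
    block <- c(block, paste0("> <", nm, ">"), as.character(items[[nm]]), "")
  block
}
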