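# Fixed-width data binning: continuous descriptor values falling in the
# same interval are replaced by per-bin summary statistics. At 1 Da MW
# resolution a bin is an "iso-MW" class - structurally diverse molecules
# of (near-)equal mass - and the bin means of price and atom counts are
# the quantities the downstream correlation analysis runs on.

#' Binning specification
#'
#' @param variable Descriptor column to bin on (default `"mw_avg"`).
#' @param resolution Bin width in the variable's units (default 1 Da).
#' @param origin Lower edge of bin 0 (default 0), so bin `k` covers the
#'   half-open interval `[origin + k*resolution, origin + (k+1)*resolution)`.
#' @param min_occupancy Occupancy threshold a bin must reach to count as
#'   stable in bin-level correlations (default 1).
#' @param representative `"center"` (lower edge + half a resolution, the
#'   default) or `"mean"` (mean of the binning variable within the bin)
#'   as the bin's x-value in bin-level correlations.
#' @return A `qser_bin_spec` list.
#' @export
bin_spec <- function(variable = "mw_avg", resolution = 1, origin = 0,
                     min_occupancy = 1L,
                     representative = c("center", "mean")) {
  stopifnot(is.numeric(resolution), resolution > 0,
            is.numeric(origin), min_occupancy >= 1)
  structure(list(variable = variable, resolution = resolution,
                 origin = origin, min_occupancy = as.integer(min_occupancy),
                 representative = match.arg(representative)),
            class = "qser_bin_spec")
}

#' Assign values to bins
#'
#' @param values Finite numeric vector.
#' @param spec A [bin_spec()].
#' @return Integer bin indices `floor((value - origin) / resolution)`.
#' @export
#' @examples
#' assign_bin(c(249.99, 250, 251.3), bin_spec(resolution = 1))
assign_bin <- function(values, spec) {
  if (any(!is.finite(values))) stop("cannot bin non-finite values")
  as.integer(floor((values - spec$origin) / spec$resolution))
}

#' Build a bin table
#'
#' Groups records by bin and computes per-bin occupancy and per-variable
#' means. Bins inside the data range that contain no record are emitted
#' with count 0 and `NA` means (flagged, never zero-filled). The mean of
#' the binning variable itself is always tracked, so the `"mean"`
#' representative is available downstream.
#'
#' @param descriptors A [compute_descriptors()] table (any data.frame
#'   with the binning variable works).
#' @param spec A [bin_spec()].
#' @param tracked Columns to average per bin; defaults to the price and
#'   atom-count descriptors present in the input.
#' @return A `qser_bin_table`: `data.table` with columns `bin`, `lower`,
#'   `upper`, `center`, `n` and one `mean_<var>` column per tracked
#'   variable; the spec is attached as attribute `"spec"`.
#' @export
build_bin_table <- function(descriptors, spec = bin_spec(),
                            tracked = NULL) {
  dt <- data.table::as.data.table(descriptors)
  if (nrow(dt) == 0L) stop("no records to bin")
  if (!spec$variable %in% names(dt))
    stop("binning variable '", spec$variable, "' not found")
  if (is.null(tracked))
    tracked <- intersect(c("price_wbm", "p2_mbm", "ac_total", "ac_c",
                           "ac_h", "ac_hetero", "sas",
                           grep("^cnt_", names(dt), value = TRUE)),
                         names(dt))
  tracked <- union(spec$variable, tracked)
  v <- dt[[spec$variable]]
  if (any(!is.finite(v))) stop("binning variable contains non-finite values")
  idx <- assign_bin(v, spec)
  work <- dt[, tracked, with = FALSE]
  work[, ".bin" := idx]
  agg <- work[, c(list(.n = .N),
                  lapply(.SD, function(col) mean(as.numeric(col)))),
              keyby = ".bin", .SDcols = tracked]
  full <- data.table::data.table(.bin = seq(min(idx), max(idx)))
  out <- agg[full, on = ".bin"]
  out[is.na(out$.n), ".n" := 0L]
  data.table::setnames(out, c(".bin", ".n"), c("bin", "n"))
  data.table::setnames(out, tracked, paste0("mean_", tracked))
  out[, "lower" := spec$origin + bin * spec$resolution]
  out[, "upper" := spec$origin + (bin + 1) * spec$resolution]
  out[, "center" := (lower + upper) / 2]
  data.table::setcolorder(out, c("bin", "lower", "upper", "center", "n"))
  out[, "n" := as.integer(n)]
  data.table::setattr(out, "spec", spec)
  data.table::setattr(out, "class", c("qser_bin_table", class(out)))
  out[]
}

#' Occupancy histogram and cumulative fractions
#'
#' @param bin_table A [build_bin_table()] result.
#' @param below Numeric cut points (in the binning variable's units);
#'   each is rounded down to the nearest bin edge and the fraction of
#'   records in bins entirely below it is reported.
#' @return List with `histogram` (`bin`, `center`, `n`) and
#'   `cumulative_below`, a named numeric vector of fractions.
#' @export
frequency_histogram <- function(bin_table, below = numeric()) {
  stopifnot(inherits(bin_table, "qser_bin_table"))
  total <- sum(bin_table$n)
  cum <- vapply(below, function(cut)
    sum(bin_table$n[bin_table$upper <= cut]) / total, numeric(1))
  names(cum) <- as.character(below)
  list(histogram = bin_table[, c("bin", "center", "n"), with = FALSE],
       cumulative_below = cum)
}

#' Bin table over the synthetic-accessibility score
#'
#' Same contract as [build_bin_table()] with SAS as the binning variable;
#' records without a SAS value are excluded and counted (scores are an
#' external column and can be missing for a handful of records).
#'
#' @param descriptors Descriptor table with a `sas` column.
#' @param spec A [bin_spec()] over `"sas"` (default resolution 0.1).
#' @return A `qser_bin_table` with attribute `"n_missing_sas"`.
#' @export
sas_bin_table <- function(descriptors,
                          spec = bin_spec("sas", resolution = 0.1)) {
  dt <- data.table::as.data.table(descriptors)
  if (!"sas" %in% names(dt)) stop("no 'sas' column present")
  missing <- !is.finite(dt$sas)
  if (all(missing)) stop("all records are missing a SAS value")
  bt <- build_bin_table(dt[!missing], spec)
  data.table::setattr(bt, "n_missing_sas", sum(missing))
  bt
}

#' Write a bin table as TSV
#'
#' One row per bin; the binning variable, resolution and origin are
#' recorded in `#`-prefixed header comments.
#'
#' @param bin_table A `qser_bin_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(bin_table, path) {
  spec <- attr(bin_table, "spec")
  hdr <- sprintf("# variable=%s resolution=%s origin=%s",
                 spec$variable, format(spec$resolution),
                 format(spec$origin))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(data.table::as.data.table(bin_table), path,
                     sep = "\t", quote = FALSE, na = "NA", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
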