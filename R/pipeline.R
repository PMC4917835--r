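#' Run the full structure-economy analysis
#'
#' Orchestrates curation, descriptor computation, the record-level
#' correlation matrix, MW bin tables at each requested resolution,
#' record-level credibility nulls (random variates and shuffled
#' prices), the nitrogen parity comparison and heteroatom price
#' profiles, writing every artifact plus a provenance manifest to
#' `output_dir`. Identical input, seed and settings give a
#' byte-identical bundle. Any stage failure removes partial outputs and
#' aborts naming the stage.
#'
#' @param input A catalogue `data.table` (columns `record_id`,
#'   `formula`, `price_wbm`, optional `sas`), or a file path.
#' @param format `"table"` or `"sdf"`; only used when `input` is a path.
#' @param output_dir Directory for the report bundle (created).
#' @param bin_resolutions MW bin widths in Da (a bin table per value).
#' @param null_runs Monte-Carlo runs for the two record-level nulls.
#' @param seed Seed for the null simulations.
#' @param sublibrary_element Element for the parity and profile
#'   analyses.
#' @param profile_elements Elements for per-count price profiles.
#' @param ... Passed to the reader when `input` is a path.
#' @return Invisibly, a list with the in-memory results (`report`,
#'   `descriptors`, `correlation`, `bin_tables`, `nulls`, `parity`,
#'   `profiles`, `manifest`).
#' @export
run_pipeline <- function(input, format = c("table", "sdf"),
                         output_dir, bin_resolutions = c(1, 2),
                         null_runs = 200L, seed = 1L,
                         sublibrary_element = "N",
                         profile_elements = c("N", "Cl"), ...) {
  format <- match.arg(format)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(fname, writer) {
    path <- file.path(output_dir, fname)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "read"
  tryCatch({
    if (is.character(input)) {
      rd <- if (format == "sdf") read_catalog_sdf(input, ...)
            else read_catalog_table(input, ...)
      catalog <- rd$catalog; report <- rd$report
    } else {
      catalog <- data.table::as.data.table(input)
      dd <- deduplicate(catalog)
      catalog <- dd$catalog
      report <- curation_report(nrow(input), nrow(catalog),
                                n_dropped_duplicates = dd$n_removed,
                                n_sas_missing =
                                  if ("sas" %in% names(catalog))
                                    sum(is.na(catalog$sas)) else nrow(catalog))
    }
    emit("curation_report.json", function(p)
      jsonlite::write_json(unclass(report), p, auto_unbox = TRUE))

    stage <- "descriptors"
    desc <- compute_descriptors(catalog)
    emit("descriptors.tsv", function(p) write_catalog(desc, p))

    stage <- "correlation_matrix"
    cm <- correlation_matrix(desc)
    emit("correlation_matrix.tsv", function(p) {
      m <- data.table::as.data.table(round(cm$r, 6), keep.rownames = "variable")
      write_catalog(m, p)
    })

    stage <- "bin_tables"
    bts <- lapply(bin_resolutions, function(res)
      build_bin_table(desc, bin_spec("mw_avg", resolution = res)))
    names(bts) <- paste0("res", bin_resolutions)
    for (i in seq_along(bts)) {
      nm <- sprintf("bin_table_res%s.tsv", bin_resolutions[i])
      local({ bt <- bts[[i]]; emit(nm, function(p) write_bin_table(bt, p)) })
    }

    stage <- "nulls"
    nulls <- list(
      random_variate = random_variate_null(desc$mw_avg, runs = null_runs,
                                           seed = seed),
      shuffled_price = shuffled_price_null(desc$mw_avg, desc$price_wbm,
                                           runs = null_runs,
                                           seed = seed + 1L))
    emit("null_results.json", function(p)
      jsonlite::write_json(lapply(nulls, function(x)
        x[c("mode", "binned", "runs", "n", "seed", "mean_abs_r",
            "sd_abs_r")]), p, auto_unbox = TRUE, digits = NA))

    stage <- "parity"
    sub <- extract_sublibrary(desc, sublibrary_spec(sublibrary_element,
                                                    chno_only = TRUE))
    parity <- if (nrow(sub)) parity_split_bins(sub) else
      data.table::data.table()
    emit("parity_comparison.tsv", function(p) write_catalog(parity, p))

    stage <- "profiles"
    profiles <- lapply(profile_elements, function(el)
      heteroatom_price_profile(desc, el))
    names(profiles) <- profile_elements
    for (el in profile_elements) {
      local({
        prof <- profiles[[el]]
        emit(sprintf("heteroatom_profile_%s.tsv", el),
             function(p) write_catalog(prof, p))
      })
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("qser")),
      seed = seed, null_runs = null_runs,
      bin_resolutions = bin_resolutions,
      n_records = nrow(desc),
      input = if (is.character(input))
        list(path = input, md5 = unname(tools::md5sum(input)))
      else list(path = NA, md5 = NA),
      outputs = stats::setNames(
        as.list(unname(tools::md5sum(written))), basename(written)))
    emit("manifest.json", function(p)
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))

    invisible(list(report = report, descriptors = desc, correlation = cm,
                   bin_tables = bts, nulls = nulls, parity = parity,
                   profiles = profiles, manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
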