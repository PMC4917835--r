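#' Curation report
#'
#' Bookkeeping for catalogue curation: every input record is either kept
#' or counted in exactly one drop category, so the counts always
#' reconcile with the input size.
#'
#' @param n_input,n_kept,n_dropped_duplicates,n_dropped_invalid_structure,n_dropped_missing_price,n_sas_missing Integer counts.
#' @param dropped_ids Character vector of dropped record identifiers.
#' @return A `qser_curation_report` list.
#' @export
curation_report <- function(n_input, n_kept, n_dropped_duplicates = 0L,
                            n_dropped_invalid_structure = 0L,
                            n_dropped_missing_price = 0L,
                            n_sas_missing = 0L, dropped_ids = character()) {
  rep <- list(n_input = as.integer(n_input), n_kept = as.integer(n_kept),
              n_dropped_duplicates = as.integer(n_dropped_duplicates),
              n_dropped_invalid_structure = as.integer(n_dropped_invalid_structure),
              n_dropped_missing_price = as.integer(n_dropped_missing_price),
              n_sas_missing = as.integer(n_sas_missing),
              dropped_ids = as.character(dropped_ids))
  stopifnot(rep$n_input == rep$n_kept + rep$n_dropped_duplicates +
              rep$n_dropped_invalid_structure + rep$n_dropped_missing_price)
  structure(rep, class = "qser_curation_report")
}

#' @export
print.qser_curation_report <- function(x, ...) {
  cat("<curation report>\n",
      " input records:      ", x$n_input, "\n",
      " kept:               ", x$n_kept, "\n",
      " dropped duplicates: ", x$n_dropped_duplicates, "\n",
      " dropped structures: ", x$n_dropped_invalid_structure, "\n",
      " dropped prices:     ", x$n_dropped_missing_price, "\n",
      " records without SAS:", x$n_sas_missing, "\n", sep = "")
  invisible(x)
}

#' Read a catalogue from an SD file (V2000)
#'
#' Each record contributes one curated row. The molecular formula comes
#' from the `mf_field` data item when present (vendor MF fields reflect
#' salts/hydrates the drawing may omit; a disagreeing connection table is
#' logged, not preferred), otherwise from the connection table with
#' implicit hydrogens. Records whose structure cannot be interpreted and
#' that carry no formula field are dropped and counted, as are records
#' without a positive price. Duplicates (same id, or same formula at the
#' same price) are removed keeping the first occurrence.
#'
#' @param path SD file path.
#' @param price_field Name of the data item holding the $/g price.
#' @param mf_field Optional name of a molecular-formula data item.
#' @param sas_field Optional name of a synthetic-accessibility data item.
#' @param quiet Suppress per-drop messages.
#' @return List with `catalog` (a `data.table`: `record_id`, `formula`,
#'   `price_wbm`, `sas`, `source_line`) and `report`
#'   (a [curation_report()]).
#' @export
read_catalog_sdf <- function(path, price_field = "PRICE", mf_field = "MF",
                             sas_field = "SAS", quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_records(lines)
  n <- length(recs)
  rows <- vector("list", n)
  inv <- 0L; nop <- 0L; dropped <- character()
  for (i in seq_len(n)) {
    rec <- recs[[i]]
    items <- sdf_data_items(rec)
    id <- trimws(rec[1L])
    if (!nzchar(id)) id <- sprintf("REC%06d", i)
    formula <- NULL
    if (!is.null(mf_field) && !is.null(items[[mf_field]])) {
      formula <- tryCatch(parse_formula(trimws(items[[mf_field]])),
                          error = function(e) NULL)
    }
    if (is.null(formula)) {
      mend <- grep("^M  END", rec)
      ctab <- if (length(mend)) rec[1:mend[1L]] else rec
      formula <- tryCatch(formula_from_ctab(ctab), error = function(e) {
        if (!quiet) message("record ", id, ": ", conditionMessage(e))
        NULL
      })
    }
    if (is.null(formula)) {
      inv <- inv + 1L; dropped <- c(dropped, id); next
    }
    price <- parse_price(items[[price_field]])
    if (is.na(price) || price <= 0) {
      nop <- nop + 1L; dropped <- c(dropped, id); next
    }
    sas <- if (!is.null(sas_field) && !is.null(items[[sas_field]]))
      suppressWarnings(as.numeric(items[[sas_field]])) else NA_real_
    rows[[i]] <- data.table::data.table(
      record_id = id, formula = format_formula(formula),
      price_wbm = price, sas = sas, source_line = i)
  }
  kept <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(kept) == 0L)
    kept <- data.table::data.table(record_id = character(),
                                   formula = character(),
                                   price_wbm = numeric(), sas = numeric(),
                                   source_line = integer())
  dd <- deduplicate(kept)
  report <- curation_report(
    n_input = n, n_kept = nrow(dd$catalog),
    n_dropped_duplicates = dd$n_removed,
    n_dropped_invalid_structure = inv, n_dropped_missing_price = nop,
    n_sas_missing = sum(is.na(dd$catalog$sas)), dropped_ids = dropped)
  list(catalog = dd$catalog, report = report)
}

#' Read a catalogue from a delimited table
#'
#' @param path CSV/TSV path (delimiter sniffed by [data.table::fread()]).
#' @param columns Named character vector mapping the required roles
#'   `record_id`, `formula`, `price_wbm` (and optionally `sas`) to column
#'   names in the file.
#' @inheritParams read_catalog_sdf
#' @return Same contract as [read_catalog_sdf()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,mf,usd_per_g", "a,C6H6,10", "b,C5H5N,12.5"), f)
#' read_catalog_table(f, c(record_id = "id", formula = "mf",
#'                         price_wbm = "usd_per_g"))$catalog
read_catalog_table <- function(path,
                               columns = c(record_id = "record_id",
                                           formula = "formula",
                                           price_wbm = "price_wbm",
                                           sas = "sas"),
                               quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(data.table::fread(path, nrows = 0L))
  need <- c("record_id", "formula", "price_wbm")
  for (role in need) {
    if (!role %in% names(columns) || is.na(columns[role]) ||
        !(columns[role] %in% header))
      stop("mapped column for '", role, "' (",
           if (role %in% names(columns)) columns[role] else "<unmapped>",
           ") not present in ", path)
  }
  charcols <- intersect(unname(columns[c("record_id", "formula")]), header)
  raw <- data.table::fread(path, colClasses = list(character = charcols))
  has_sas <- "sas" %in% names(columns) && columns["sas"] %in% names(raw)
  n <- nrow(raw)
  cat0 <- data.table::data.table(
    record_id = as.character(raw[[columns["record_id"]]]),
    formula = as.character(raw[[columns["formula"]]]),
    price_raw = as.character(raw[[columns["price_wbm"]]]),
    sas = if (has_sas) suppressWarnings(as.numeric(raw[[columns["sas"]]]))
          else NA_real_,
    source_line = seq_len(n) + 1L)
  price <- vapply(cat0$price_raw, parse_price, numeric(1), USE.NAMES = FALSE)
  price_ok <- !is.na(price) & price > 0
  counts <- parse_formula_counts(cat0$formula)
  formula_ok <- attr(counts, "valid")
  # rows failing the fast tokeniser get one scalar-parse retry (handles
  # repeated element tokens)
  for (i in which(!formula_ok)) {
    f <- tryCatch(parse_formula(cat0$formula[i]), error = function(e) NULL)
    if (!is.null(f)) {
      cat0[i, "formula" := format_formula(f)]
      formula_ok[i] <- TRUE
    }
  }
  keep <- formula_ok & price_ok
  dropped <- cat0$record_id[!keep]
  kept <- cat0[keep]
  kept[, "price_wbm" := price[keep]]
  kept[, "price_raw" := NULL]
  data.table::setcolorder(kept, c("record_id", "formula", "price_wbm",
                                  "sas", "source_line"))
  dd <- deduplicate(kept)
  report <- curation_report(
    n_input = n, n_kept = nrow(dd$catalog),
    n_dropped_duplicates = dd$n_removed,
    n_dropped_invalid_structure = sum(!formula_ok),
    n_dropped_missing_price = sum(formula_ok & !price_ok),
    n_sas_missing = sum(is.na(dd$catalog$sas)), dropped_ids = dropped)
  if (!quiet && length(dropped))
    message(length(dropped), " record(s) dropped during curation")
  list(catalog = dd$catalog, report = report)
}

#' Remove duplicate catalogue records
#'
#' A record is a duplicate when its `record_id` was already seen, or when
#' an identical (formula, price) pair was. The first occurrence wins and
#' input order is preserved.
#'
#' @param catalog A catalogue `data.table`.
#' @param key `"id_or_pair"` (default) or `"id"` (identifier only).
#' @return List with the deduplicated `catalog` and `n_removed`.
#' @export
deduplicate <- function(catalog, key = c("id_or_pair", "id")) {
  key <- match.arg(key)
  catalog <- data.table::as.data.table(catalog)
  if (nrow(catalog) == 0L) return(list(catalog = catalog, n_removed = 0L))
  dup <- duplicated(catalog$record_id)
  if (key == "id_or_pair")
    dup <- dup | duplicated(paste(catalog$formula, catalog$price_wbm,
                                  sep = "\r"))
  list(catalog = catalog[!dup], n_removed = sum(dup))
}

#' Write a catalogue (or any result table) as TSV
#'
#' Deterministic, byte-stable output: writing, re-reading with
#' [read_catalog_table()] and writing again yields an identical file.
#'
#' @param catalog A `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  data.table::fwrite(data.table::as.data.table(catalog), path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a catalogue as a minimal SD file
#'
#' Emits one record per row with a zero-atom connection table and the
#' formula, price and SAS carried as `MF`, `PRICE` and `SAS` data items,
#' which is exactly the path [read_catalog_sdf()] resolves formula-only
#' vendor records through. Intended for reader round-trip tests, not for
#' structure exchange.
#'
#' @param catalog A catalogue `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_sdf <- function(catalog, path) {
  catalog <- data.table::as.data.table(catalog)
  blocks <- vapply(seq_len(nrow(catalog)), function(i) {
    r <- catalog[i]
    sas_part <- if (!is.null(r$sas) && !is.na(r$sas))
      sprintf("> <SAS>\n%s\n\n", format(r$sas, digits = 15)) else ""
    sprintf(paste0("%s\n  qser\n\n",
                   "  0  0  0  0  0  0  0  0  0  0999 V2000\nM  END\n",
                   "> <MF>\n%s\n\n> <PRICE>\n%s\n\n%s$$$$"),
            r$record_id, r$formula, format(r$price_wbm, digits = 15),
            sas_part)
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}
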