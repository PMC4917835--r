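#' Parse a molecular formula
#'
#' Parses a flat Hill-style molecular formula (element symbol followed by
#' an optional positive integer count, e.g. `"C9H13N3O"`) into a named
#' count vector. Repeated element tokens are summed. Parenthesised
#' groups, hydrates, charges and isotope labels are not part of the
#' grammar and are rejected.
#'
#' @param text A single non-empty formula string.
#' @param allowed Character vector of permitted element symbols.
#' @return Named integer vector of atom counts (class `molecular_formula`),
#'   ordered in Hill convention (C, H, then alphabetical).
#' @export
#' @examples
#' parse_formula("C6H6")
#' parse_formula("C9H13N3O")
parse_formula <- function(text, allowed = allowed_elements()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("formula '", text, "' contains characters outside the ",
         "element-count grammar")
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  bad <- setdiff(syms, allowed)
  if (length(bad))
    stop("unknown element symbol(s) in '", text, "': ",
         paste(unique(bad), collapse = ", "))
  if (anyNA(counts) || any(counts < 1L))
    stop("formula '", text, "' has a zero or unreadable element count")
  out <- vapply(split(counts, syms), sum, integer(1))
  structure(as.integer(out[hill_order(names(out))]),
            names = hill_order(names(out)),
            class = "molecular_formula")
}

hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  c(intersect(c("C", "H"), symbols), rest)
}

#' Format a molecular formula in Hill notation
#'
#' @param formula Named integer vector of atom counts.
#' @return A single formula string; counts of 1 are elided.
#' @export
#' @examples
#' format_formula(c(C = 9L, H = 13L, N = 3L, O = 1L))
format_formula <- function(formula) {
  counts <- unclass(formula)
  counts <- counts[counts > 0]
  ord <- hill_order(names(counts))
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Molecular weight of a formula
#'
#' Weighted sum of element masses. `"average"` uses standard atomic
#' weights (the MW used for molar price conversion and MW binning);
#' `"nominal"` uses most-abundant-isotope integer masses (the MW whose
#' parity the nitrogen rule constrains).
#'
#' @param formula Named count vector as returned by [parse_formula()].
#' @param mode `"average"` or `"nominal"`.
#' @param table A [mass_table()].
#' @return Molecular weight in Da; integer-valued in nominal mode.
#' @export
#' @examples
#' molecular_weight(parse_formula("C6H6"), "nominal")  # 78
#' molecular_weight(parse_formula("C6H6"), "average")  # 78.114
molecular_weight <- function(formula, mode = c("average", "nominal"),
                             table = mass_table()) {
  mode <- match.arg(mode)
  counts <- unclass(formula)
  missing <- setdiff(names(counts), names(table[[mode]]))
  if (length(missing))
    stop("element(s) missing from mass table: ",
         paste(missing, collapse = ", "))
  sum(counts * table[[mode]][names(counts)])
}

#' Atom counts of a formula
#'
#' @param formula Named count vector as returned by [parse_formula()].
#' @return List with `ac_total`, `ac_c`, `ac_h`, `ac_hetero` (all atoms
#'   that are neither carbon nor hydrogen) and the `per_element` counts.
#' @export
#' @examples
#' atom_counts(parse_formula("C9H13N3O"))
atom_counts <- function(formula) {
  counts <- unclass(formula)
  ac_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  ac_h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  total <- sum(counts)
  list(ac_total = as.integer(total), ac_c = as.integer(ac_c),
       ac_h = as.integer(ac_h),
       ac_hetero = as.integer(total - ac_c - ac_h),
       per_element = counts)
}

#' Nitrogen-rule consistency of a record
#'
#' For molecules built only of C, H, N and O, the parity of the nominal
#' (integer) molecular mass equals the parity of the nitrogen count: C,
#' O (even mass, even valence) and H (odd mass, odd valence) cannot break
#' parity, while each N (mass 14, valence 3) flips the hydrogen count but
#' not its own even mass. A violation therefore flags a corrupt record.
#'
#' @param mw_nominal Integer nominal molecular weight(s).
#' @param n_count Nitrogen atom count(s).
#' @param chno_only Logical: is the composition restricted to C/H/N/O?
#' @return Character vector in `"consistent"`, `"inconsistent"`,
#'   `"not_applicable"` (the latter whenever `chno_only` is `FALSE`).
#' @export
#' @examples
#' nitrogen_parity(179, 3, TRUE)  # "consistent"
nitrogen_parity <- function(mw_nominal, n_count, chno_only) {
  out <- ifelse(!chno_only, "not_applicable",
                ifelse(mw_nominal %% 2 == n_count %% 2,
                       "consistent", "inconsistent"))
  as.character(out)
}

# Vectorised Hill-formula tokeniser for catalogue-scale inputs. Assumes
# each element symbol appears at most once per formula (true of Hill
# notation); rows violating that, or containing foreign characters, are
# flagged in the "valid" attribute and must be re-parsed or dropped by
# the caller.
parse_formula_counts <- function(formulas, allowed = allowed_elements()) {
  n <- length(formulas)
  counts <- matrix(0L, nrow = n, ncol = length(allowed),
                   dimnames = list(NULL, allowed))
  matched_chars <- integer(n)
  two <- allowed[nchar(allowed) == 2L]
  one <- allowed[nchar(allowed) == 1L]
  for (sym in c(two, one)) {
    pat <- if (nchar(sym) == 2L) paste0(sym, "([0-9]*)")
           else paste0(sym, "(?![a-z])([0-9]*)")
    m <- regexpr(pat, formulas, perl = TRUE)
    hit <- m > 0L
    if (!any(hit)) next
    len <- attr(m, "match.length")[hit]
    tok <- substr(formulas[hit], m[hit], m[hit] + len - 1L)
    num <- substr(tok, nchar(sym) + 1L, nchar(tok))
    counts[hit, sym] <- ifelse(nzchar(num),
                               suppressWarnings(as.integer(num)), 1L)
    matched_chars[hit] <- matched_chars[hit] + len
  }
  valid <- !is.na(formulas) & nzchar(formulas) &
    matched_chars == nchar(formulas) &
    !matrixStats_anyNA_rows(counts) & rowSums(counts) > 0L
  attr(counts, "valid") <- valid
  counts
}

matrixStats_anyNA_rows <- function(m) rowSums(is.na(m)) > 0L

#' Compute per-record molecular descriptors
#'
#' Parses the formula column of a catalogue and derives, for every
#' record, average and nominal molecular weight, atom counts (total,
#' carbon, hydrogen, heteroatom, per element), nominal-mass and nitrogen
#' parities, the C/H/N/O-only flag, and the molar price
#' `p2_mbm = price_wbm * mw_avg` when a weight-based price is present.
#'
#' @param catalog A data.table/data.frame with at least `record_id` and
#'   `formula` columns; `price_wbm` and `sas` are carried through when
#'   present.
#' @param table A [mass_table()].
#' @return A `data.table` with one row per record, class
#'   `qser_descriptors`. Rows whose formula cannot be parsed are dropped
#'   with a warning naming the count.
#' @export
#' @examples
#' cat <- data.frame(record_id = "r1", formula = "C6H6", price_wbm = 10)
#' compute_descriptors(cat)
compute_descriptors <- function(catalog, table = mass_table()) {
  catalog <- data.table::as.data.table(catalog)
  stopifnot(all(c("record_id", "formula") %in% names(catalog)))
  counts <- parse_formula_counts(catalog$formula)
  valid <- attr(counts, "valid")
  if (!all(valid)) {
    warning(sum(!valid), " record(s) with unparseable formulas dropped")
    catalog <- catalog[valid]
    counts <- counts[valid, , drop = FALSE]
  }
  tab <- mass_table_matrix(table, colnames(counts))
  mw_avg <- as.vector(counts %*% tab$average)
  mw_nominal <- as.integer(round(counts %*% tab$nominal))
  ac_c <- counts[, "C"]
  ac_h <- counts[, "H"]
  ac_total <- as.integer(rowSums(counts))
  hetero_cols <- setdiff(colnames(counts), c("C", "H"))
  chno_only <- rowSums(counts[, setdiff(hetero_cols, c("N", "O")),
                              drop = FALSE]) == 0L
  out <- data.table::data.table(
    record_id = catalog$record_id,
    formula = catalog$formula,
    mw_avg = mw_avg,
    mw_nominal = mw_nominal,
    ac_total = ac_total,
    ac_c = as.integer(ac_c),
    ac_h = as.integer(ac_h),
    ac_hetero = as.integer(ac_total - ac_c - ac_h),
    chno_only = chno_only,
    mw_parity = ifelse(mw_nominal %% 2L == 0L, "even", "odd"),
    n_parity = ifelse(counts[, "N"] %% 2L == 0L, "even", "odd")
  )
  for (el in setdiff(colnames(counts), c("C", "H")))
    data.table::set(out, j = paste0("cnt_", el), value = as.integer(counts[, el]))
  if ("price_wbm" %in% names(catalog)) {
    out[, "price_wbm" := catalog$price_wbm]
    out[, "p2_mbm" := catalog$price_wbm * mw_avg]
  }
  if ("sas" %in% names(catalog)) out[, "sas" := catalog$sas]
  data.table::setattr(out, "class", c("qser_descriptors", class(out)))
  out[]
}

mass_table_matrix <- function(table, symbols) {
  list(average = table$average[symbols], nominal = table$nominal[symbols])
}
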