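# Minimal V2000 molfile handling. Only what catalogue curation needs:
# atom symbols, bond orders, charges, data items. V3000 is rejected
# explicitly; zero-atom connection tables are legal (some vendors ship
# formula-only records) and resolve through the MF property field.

#' Derive a molecular formula from a V2000 connection table
#'
#' Counts explicit atoms from the atom block and adds implicit hydrogens
#' per heavy atom as `max(0, valence - explicit bond order sum - |charge|)`,
#' using the standard organic valence model (C:4, N:3, O:2, S:2/4/6
#' lowest feasible, halogens:1, Se:2, P:3/5 lowest feasible). Charges are
#' taken from `M  CHG` property lines when present, else from the legacy
#' atom-block charge column.
#'
#' @param ctab Character vector: the lines of one molfile (header through
#'   `M  END`).
#' @param allowed Permitted element symbols.
#' @return A `molecular_formula` count vector.
#' @export
#' @examples
#' # methane: one unbonded carbon gains four implicit hydrogens
#' block <- c("methane", "", "",
#'            "  1  0  0  0  0  0  0  0  0  0999 V2000",
#'   "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
#'            "M  END")
#' format_formula(formula_from_ctab(block))
formula_from_ctab <- function(ctab, allowed = allowed_elements()) {
  if (length(ctab) < 4L) stop("connection table shorter than 4 lines")
  counts_line <- ctab[4L]
  if (grepl("V3000", counts_line, fixed = TRUE))
    stop("V3000 connection tables are not supported")
  natoms <- suppressWarnings(as.integer(substr(counts_line, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts_line, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L)
    stop("malformed counts line (line 4): '", counts_line, "'")
  if (natoms == 0L)
    stop("connection table has no atoms")
  if (length(ctab) < 4L + natoms + nbonds)
    stop("connection table truncated: expected ", natoms, " atom and ",
         nbonds, " bond lines after line 4")
  atom_lines <- ctab[4L + seq_len(natoms)]
  symbols <- trimws(substr(atom_lines, 32L, 34L))
  bad <- setdiff(symbols, allowed)
  if (length(bad))
    stop("unsupported element(s) in atom block: ",
         paste(unique(bad), collapse = ", "))
  # legacy charge column: 1..7 encode +3..-3 (4 = doublet radical)
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  chg_code[is.na(chg_code)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg_code + 1L]
  mchg <- grep("^M  CHG", ctab, value = TRUE)
  if (length(mchg)) {
    charge[] <- 0L  # M CHG supersedes all atom-block charges
    for (line in mchg) {
      f <- scan(text = substr(line, 7L, nchar(line)), what = integer(),
                quiet = TRUE)
      k <- f[1L]
      pairs <- matrix(f[-1L], ncol = 2L, byrow = TRUE)[seq_len(k), ,
                                                       drop = FALSE]
      charge[pairs[, 1L]] <- pairs[, 2L]
    }
  }
  degree <- numeric(natoms)
  if (nbonds > 0L) {
    bond_lines <- ctab[4L + natoms + seq_len(nbonds)]
    a1 <- as.integer(substr(bond_lines, 1L, 3L))
    a2 <- as.integer(substr(bond_lines, 4L, 6L))
    ord <- as.integer(substr(bond_lines, 7L, 9L))
    if (anyNA(a1) || anyNA(a2) || anyNA(ord) ||
        any(a1 < 1L | a1 > natoms | a2 < 1L | a2 > natoms))
      stop("malformed bond block")
    # aromatic bonds (order 4) counted as 1.5; a benzene carbon then has
    # degree 4 after rounding at the valence comparison
    ordv <- ifelse(ord == 4L, 1.5, as.numeric(ord))
    for (i in seq_len(nbonds)) {
      degree[a1[i]] <- degree[a1[i]] + ordv[i]
      degree[a2[i]] <- degree[a2[i]] + ordv[i]
    }
  }
  degree <- as.integer(ceiling(degree - 1e-9))
  implicit <- integer(natoms)
  for (i in seq_len(natoms)) {
    states <- .VALENCES[[symbols[i]]]
    need <- degree[i] + abs(charge[i])
    feasible <- states[states >= need]
    if (!length(feasible)) {
      if (need > max(states))
        stop("atom ", i, " (", symbols[i], ") exceeds its maximum valence")
      feasible <- max(states)
    }
    implicit[i] <- min(feasible) - need
  }
  tot <- table(symbols)
  counts <- stats::setNames(as.integer(tot), names(tot))
  h <- sum(implicit) + if ("H" %in% names(counts)) counts[["H"]] else 0L
  counts <- counts[names(counts) != "H"]
  if (h > 0L) counts <- c(counts, H = as.integer(h))
  ord <- hill_order(names(counts))
  structure(as.integer(counts[ord]), names = ord,
            class = "molecular_formula")
}

# Split an SD file into records at "$$$$" delimiters; returns a list of
# character vectors (one per record, delimiter excluded).
split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (!length(ends)) {
    if (!length(lines)) return(list())
    ends <- length(lines)
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) {
    r <- lines[s:e]
    r[!grepl("^\\$\\$\\$\\$\\s*$", r)]
  }, starts, ends)
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

# Extract "> <NAME>" data items from the property part of one record.
sdf_data_items <- function(rec) {
  hdr <- grep("^>\\s*<", rec)
  items <- list()
  for (h in hdr) {
    name <- sub("^>\\s*<([^>]+)>.*$", "\\1", rec[h])
    val <- character()
    i <- h + 1L
    while (i <= length(rec) && nzchar(trimws(rec[i]))) {
      val <- c(val, rec[i]); i <- i + 1L
    }
    items[[name]] <- paste(val, collapse = "\n")
  }
  items
}

parse_price <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_real_)
  x <- trimws(x)
  x <- sub("^[$€£]", "", x)
  x <- sub("[$€£]$", "", trimws(x))
  if (grepl(",", x, fixed = TRUE)) return(NA_real_)  # thousands separators rejected
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || !is.finite(v)) NA_real_ else v
}
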