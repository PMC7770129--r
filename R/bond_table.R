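# Bond-energy lookup table: (element, element, bond order) -> kJ/mol.

#' Load a bond-energy table
#'
#' Reads a delimited text file mapping a bond type (two element symbols plus
#' an integer bond order) to an average bond energy in kJ/mol. The field
#' separator (comma or tab) is auto-detected from the header line; lines
#' starting with `#` are ignored. The two element symbols of a key are
#' unordered: rows `C,H,1` and `H,C,1` denote the same bond and are
#' canonicalized on load.
#'
#' @param path path to a delimited text file with header columns
#'   `element_a, element_b, order, energy_kj_mol`.
#' @param strict if `TRUE`, symmetric duplicate rows carrying conflicting
#'   energies are an error; otherwise the last row wins with a warning.
#' @param source_name provenance label stored with the table and echoed into
#'   every result computed from it. Defaults to the file name.
#' @return A `bond_energy_table`: a data frame with canonicalized columns
#'   `element_a`, `element_b`, `order`, `energy_kj_mol` and a `source_name`
#'   attribute.
#' @seealso [default_bond_table()], [lookup_energy()], [write_bond_table()]
#' @export
load_bond_table <- function(path, strict = FALSE, source_name = basename(path)) {
  if (!file.exists(path)) stop("bond table file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("bond table has no data rows: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- trimws(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]])
  expected <- c("element_a", "element_b", "order", "energy_kj_mol")
  if (!identical(tolower(header), expected)) {
    stop("bond table header must be `", paste(expected, collapse = ", "),
         "`, got `", paste(header, collapse = ", "), "`", call. = FALSE)
  }
  fields <- strsplit(lines[-1L], sep, fixed = TRUE)
  rows_no <- line_no[-1L]
  n_fields <- lengths(fields)
  if (any(n_fields != 4L)) {
    stop("malformed bond table row at line ", rows_no[which(n_fields != 4L)[1L]],
         ": expected 4 fields", call. = FALSE)
  }
  m <- matrix(trimws(unlist(fields)), ncol = 4L, byrow = TRUE)
  order <- suppressWarnings(as.integer(m[, 3L]))
  energy <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(order) || anyNA(energy)) {
    bad <- which(is.na(order) | is.na(energy))[1L]
    stop("malformed bond table row at line ", rows_no[bad],
         ": order and energy_kj_mol must be numeric", call. = FALSE)
  }
  if (any(!order %in% 1:3)) {
    bad <- which(!order %in% 1:3)[1L]
    stop("invalid bond order ", order[bad], " at line ", rows_no[bad],
         ": bond order must be 1, 2 or 3", call. = FALSE)
  }
  if (any(energy <= 0)) {
    bad <- which(energy <= 0)[1L]
    stop("non-positive bond energy at line ", rows_no[bad],
         ": bond energies are breaking energies and must be > 0", call. = FALSE)
  }
  ea <- normalize_element(m[, 1L])
  eb <- normalize_element(m[, 2L])
  # canonical key: element pair sorted alphabetically
  swap <- ea > eb
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  tab <- data.frame(element_a = ea, element_b = eb, order = order,
                    energy_kj_mol = energy, stringsAsFactors = FALSE)
  key <- paste(tab$element_a, tab$element_b, tab$order, sep = "|")
  if (anyDuplicated(key)) {
    conflict <- vapply(split(tab$energy_kj_mol, key),
                       function(e) length(unique(e)) > 1L, logical(1L))
    if (any(conflict)) {
      msg <- paste("conflicting duplicate bond table entries:",
                   paste(names(conflict)[conflict], collapse = "; "))
      if (strict) stop(msg, call. = FALSE)
      warning(msg, " -- keeping the last occurrence", call. = FALSE)
    }
    tab <- tab[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  tab <- tab[order(tab$element_a, tab$element_b, tab$order), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, source_name = source_name,
            class = c("bond_energy_table", "data.frame"))
}

#' Default bond-energy table shipped with the package
#'
#' A table of average bond enthalpies (gas phase, 298 K) transcribed from the
#' standard general-chemistry reference tables, covering the bonds of common
#' organic and drug-like molecules (C, H, N, O, S, P, Si, halogens).
#'
#' @return A `bond_energy_table` with `source_name`
#'   `"nbescore default: average bond enthalpies at 298 K"`.
#' @export
default_bond_table <- function() {
  path <- system.file("extdata", "bond_energies_default.csv",
                      package = "nbescore", mustWork = TRUE)
  load_bond_table(path,
                  source_name = "nbescore default: average bond enthalpies at 298 K")
}

#' Look up the energy of a bond
#'
#' Symmetric in the two elements: `lookup_energy(t, "C", "H", 1)` and
#' `lookup_energy(t, "H", "C", 1)` return the same value. A bond absent from
#' the table yields `NA` (never 0), so missing energies are distinguishable
#' from zero-energy bonds, which do not exist.
#'
#' @param table a `bond_energy_table`.
#' @param element_a,element_b element symbols (vectorized, recycled).
#' @param order integer bond order(s) in `{1, 2, 3}`.
#' @return Numeric vector of energies in kJ/mol, `NA` where the key is absent.
#' @examples
#' \dontrun{
#' tab <- default_bond_table()
#' lookup_energy(tab, "C", "H", 1)
#' }
#' @export
lookup_energy <- function(table, element_a, element_b, order) {
  stopifnot(inherits(table, "bond_energy_table"))
  ea <- normalize_element(element_a)
  eb <- normalize_element(element_b)
  n <- max(length(ea), length(eb), length(order))
  ea <- rep_len(ea, n); eb <- rep_len(eb, n); order <- rep_len(as.integer(order), n)
  if (any(!order %in% 1:3)) {
    stop("bond order must be 1, 2 or 3", call. = FALSE)
  }
  swap <- ea > eb
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  key <- paste(ea, eb, order, sep = "|")
  tab_key <- paste(table$element_a, table$element_b, table$order, sep = "|")
  table$energy_kj_mol[match(key, tab_key)]
}

#' Write a bond-energy table to file
#'
#' Writes the canonical entry set as comma-separated text so that
#' `load_bond_table(write_bond_table(tab, f))` round-trips exactly.
#'
#' @param table a `bond_energy_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bond_table <- function(table, path) {
  stopifnot(inherits(table, "bond_energy_table"))
  utils::write.table(as.data.frame(table), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.bond_energy_table <- function(x, ...) {
  cat("Bond energy table:", attr(x, "source_name"), "\n")
  cat(nrow(x), "canonical entries\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
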