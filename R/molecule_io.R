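# Molecule input: SDF (V2000) and SMILES, via OpenBabel (ChemmineOB) for
# structure preparation and ChemmineR for connection-table access.
#
# Preparation = explicit hydrogens + kekulization, so that every bond
# reaching the energy lookup has an integer order in {1, 2, 3}.

#' Prepare a raw structure for bond enumeration
#'
#' Converts a single SMILES string or SDF (V2000) record into a normalized
#' SDF record in which all hydrogens are explicit atoms and aromatic systems
#' are kekulized to alternating single/double bonds.
#'
#' @param input a single SMILES string, or the text of one SDF record.
#' @param from input format, `"smiles"` or `"sdf"`.
#' @param largest_fragment if `TRUE`, strip all but the largest connected
#'   fragment (removes counterions from salts). By default every fragment of
#'   the input is kept.
#' @return The prepared SDF record as a single character string.
#' @export
prepare_molecule <- function(input, from = c("smiles", "sdf"),
                             largest_fragment = FALSE) {
  from <- match.arg(from)
  stopifnot(is.character(input), length(input) == 1L)
  ops <- "h"
  if (largest_fragment) ops <- c(ops, "r")
  opts <- data.frame(names = ops, args = rep("", length(ops)),
                     stringsAsFactors = FALSE)
  src <- if (from == "smiles") "SMI" else "SDF"
  txt <- if (from == "sdf" && !grepl("\\$\\$\\$\\$", input)) {
    paste0(input, "\n$$$$\n")
  } else input
  out <- tryCatch(
    ChemmineOB::convertFormat(src, "SDF", source = txt, options = opts),
    error = function(e) "")
  if (!nzchar(trimws(out))) {
    stop("structure could not be prepared (parse/sanitization failure)",
         call. = FALSE)
  }
  # trim trailing whitespace so prepared records concatenate cleanly
  sub("\\s+$", "", out)
}

# Parse a list of prepared SDF record texts into molecule records.
# Records are OpenBabel output, so the connection tables are well-formed.
.records_from_prepared <- function(texts, ids, source_format) {
  stopifnot(length(texts) == length(ids))
  lapply(seq_along(texts), function(i) {
    parsed <- .read_prepared_record(texts[[i]], ids[[i]])
    elements <- parsed$elements
    bb <- parsed$bonds
    iso <- .parse_m_iso(texts[[i]])
    mass_numbers <- rep(NA_integer_, length(elements))
    if (nrow(iso)) mass_numbers[iso$atom] <- iso$mass_number
    bonds <- if (is.matrix(bb) && nrow(bb) > 0L) {
      data.frame(element_a = elements[bb[, 1L]],
                 element_b = elements[bb[, 2L]],
                 order = as.integer(bb[, 3L]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(element_a = character(), element_b = character(),
                 order = integer(), stringsAsFactors = FALSE)
    }
    if (nrow(bonds) && any(!bonds$order %in% 1:3)) {
      stop("molecule '", ids[[i]], "' has a bond of unsupported order ",
           bonds$order[!bonds$order %in% 1:3][1L],
           " after preparation (only orders 1-3 are defined)", call. = FALSE)
    }
    structure(list(id = as.character(ids[[i]]),
                   bonds = bonds,
                   mw = sum(.atom_mass(elements, mass_numbers)),
                   n_atoms = length(elements),
                   elements = elements,
                   source_format = source_format),
              class = "molecule_record")
  })
}

# Read one prepared (OpenBabel-written) V2000 record. ChemmineR does the
# connection-table parsing; molecules with zero bonds (single atoms), which
# ChemmineR's SDF validation rejects, fall back to reading the atom block
# directly from the fixed-format record.
.read_prepared_record <- function(text, id) {
  lines <- strsplit(sub("\\s+$", "", text), "\n", fixed = TRUE)[[1L]]
  counts_at <- grep("V2000\\s*$", lines)[1L]
  if (is.na(counts_at)) stop("not a V2000 record (id '", id, "')", call. = FALSE)
  n_atoms <- as.integer(substr(lines[counts_at], 1L, 3L))
  n_bonds <- as.integer(substr(lines[counts_at], 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop("record has no atoms (id '", id, "')", call. = FALSE)
  }
  if (identical(n_bonds, 0L)) {
    atom_lines <- lines[(counts_at + 1L):(counts_at + n_atoms)]
    elements <- normalize_element(vapply(strsplit(trimws(atom_lines),
                                                  "\\s+"), `[[`, "", 4L))
    return(list(elements = elements,
                bonds = matrix(integer(), ncol = 3L)))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  if (length(sdfset) != 1L) {
    stop("expected exactly one record (id '", id, "')", call. = FALSE)
  }
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  list(elements = normalize_element(sub("_.*$", "", rownames(ab))),
       bonds = ChemmineR::bondblock(sdf))
}

# "M  ISO  n  aaa vvv ..." -> data.frame(atom, mass_number)
.parse_m_iso <- function(record_text) {
  lines <- grep("^M  ISO", strsplit(record_text, "\n", fixed = TRUE)[[1L]],
                value = TRUE)
  out <- data.frame(atom = integer(), mass_number = integer())
  for (ln in lines) {
    v <- as.integer(strsplit(trimws(sub("^M  ISO", "", ln)), "\\s+")[[1L]])
    n <- v[1L]
    pairs <- matrix(v[-1L], ncol = 2L, byrow = TRUE)[seq_len(n), , drop = FALSE]
    out <- rbind(out, data.frame(atom = pairs[, 1L], mass_number = pairs[, 2L]))
  }
  out
}

.finish_molecule_set <- function(records, skipped, what) {
  if (length(records) == 0L) {
    stop("no parseable molecules in ", what,
         if (skipped > 0L) paste0(" (", skipped, " record(s) failed)") else "",
         call. = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " record(s) in ", what,
            " failed preparation and were skipped", call. = FALSE)
  }
  structure(records, n_skipped = skipped, class = "molecule_set")
}

#' Parse molecules from an SDF file
#'
#' Reads a (possibly multi-record) SDF V2000 file, prepares every record
#' (explicit hydrogens, kekulization) and returns one [molecule
#' record][enumerate_bonds] per parseable entry. Records that fail
#' sanitization are skipped with a warning and counted in the `n_skipped`
#' attribute, never silently dropped.
#'
#' @param path path to an SDF file.
#' @param largest_fragment strip counterions, see [prepare_molecule()].
#' @return A `molecule_set`: list of `molecule_record`s with attribute
#'   `n_skipped`. Zero parseable records is an error.
#' @export
parse_sdf <- function(path, largest_fragment = FALSE) {
  if (!file.exists(path)) stop("SDF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("no parseable molecules in ", path, ": file is empty", call. = FALSE)
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) {
    starts <- 1L; ends <- length(lines)
  } else {
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    last <- ends[length(ends)]
    if (last < length(lines) &&
        any(nzchar(trimws(lines[(last + 1L):length(lines)])))) {
      starts <- c(starts, last + 1L); ends <- c(ends, length(lines))
    }
  }
  records <- list(); ids <- character(); skipped <- 0L
  for (k in seq_along(starts)) {
    rec_lines <- lines[starts[k]:ends[k]]
    if (all(!nzchar(trimws(setdiff(rec_lines, "$$$$"))))) next
    # realign records preceded by stray blank lines: the counts line
    # ("... V2000") is the 4th line of a well-formed molfile
    v <- grep("V2000\\s*$", rec_lines)[1L]
    if (!is.na(v) && v > 4L &&
        all(!nzchar(trimws(rec_lines[seq_len(v - 4L)])))) {
      rec_lines <- rec_lines[(v - 3L):length(rec_lines)]
    }
    rec <- paste(rec_lines, collapse = "\n")
    title <- trimws(rec_lines[1L])
    id <- if (nzchar(title) && title != "$$$$") title else as.character(k)
    prepared <- tryCatch(prepare_molecule(rec, from = "sdf",
                                          largest_fragment = largest_fragment),
                         error = function(e) NULL)
    if (is.null(prepared)) { skipped <- skipped + 1L; next }
    mol <- tryCatch(.records_from_prepared(list(prepared), list(id), "sdf")[[1L]],
                    error = function(e) NULL)
    if (is.null(mol)) { skipped <- skipped + 1L; next }
    records[[length(records) + 1L]] <- mol
  }
  .finish_molecule_set(records, skipped, path)
}

#' Parse molecules from SMILES
#'
#' One molecule per line: the SMILES string optionally followed by a
#' whitespace-separated identifier (which may contain spaces). Lines starting
#' with `#` and blank lines are ignored. The identifier defaults to the line
#' number. Invalid SMILES are skipped with a warning and counted.
#'
#' @param path path to a SMILES file; mutually exclusive with `text`.
#' @param text character vector of SMILES lines, as an alternative to `path`.
#' @param largest_fragment strip counterions, see [prepare_molecule()].
#' @return A `molecule_set`, as for [parse_sdf()].
#' @examples
#' \dontrun{
#' mols <- parse_smiles(text = c("CCO ethanol", "c1ccccc1 benzene"))
#' }
#' @export
parse_smiles <- function(path = NULL, text = NULL, largest_fragment = FALSE) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of `path` or `text`", call. = FALSE)
  }
  what <- if (is.null(path)) "SMILES input" else path
  if (!is.null(path)) {
    if (!file.exists(path)) stop("SMILES file not found: ", path, call. = FALSE)
    text <- readLines(path, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  records <- list(); skipped <- 0L
  for (k in which(keep)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    smi <- tok[1L]
    id <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ") else as.character(k)
    prepared <- tryCatch(prepare_molecule(smi, from = "smiles",
                                          largest_fragment = largest_fragment),
                         error = function(e) NULL)
    if (is.null(prepared)) { skipped <- skipped + 1L; next }
    mol <- tryCatch(.records_from_prepared(list(prepared), list(id), "smiles")[[1L]],
                    error = function(e) NULL)
    if (is.null(mol)) { skipped <- skipped + 1L; next }
    records[[length(records) + 1L]] <- mol
  }
  if (length(records) == 0L && sum(keep) == 0L) {
    stop("no parseable molecules in ", what, ": input is empty", call. = FALSE)
  }
  .finish_molecule_set(records, skipped, what)
}

#' Enumerate the bonds of a prepared molecule
#'
#' @param molecule a `molecule_record` from [parse_sdf()]/[parse_smiles()],
#'   or a prepared SDF record string from [prepare_molecule()].
#' @return A data frame with one row per bond: `element_a`, `element_b`,
#'   `order`. The multiset of rows is independent of atom numbering.
#' @export
enumerate_bonds <- function(molecule) {
  if (inherits(molecule, "molecule_record")) return(molecule$bonds)
  if (is.character(molecule) && length(molecule) == 1L) {
    return(.records_from_prepared(list(molecule), list("molecule"),
                                  "sdf")[[1L]]$bonds)
  }
  stop("`molecule` must be a molecule_record or a prepared SDF string",
       call. = FALSE)
}

#' Molecular weight of a prepared molecule
#'
#' Sum of standard atomic weights over all atoms, hydrogens included;
#' isotope-labeled atoms (SDF `M  ISO`) contribute the isotope mass.
#'
#' @inheritParams enumerate_bonds
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(molecule) {
  if (is.character(molecule) && length(molecule) == 1L) {
    molecule <- .records_from_prepared(list(molecule), list("molecule"),
                                       "sdf")[[1L]]
  }
  stopifnot(inherits(molecule, "molecule_record"))
  molecule$mw
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> id:", x$id, "|", x$n_atoms, "atoms,",
      nrow(x$bonds), "bonds, MW", format(x$mw), "g/mol\n")
  invisible(x)
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("<molecule_set>", length(x), "molecules (",
      attr(x, "n_skipped"), "skipped )\n")
  invisible(x)
}
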