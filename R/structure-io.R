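# structure_io: molecular structure input and residue-range patch selection.
#
# Atom sets are plain data frames (one row per atom) with class "atomset",
# columns: serial, name, resname, chain, resno, x, y, z, radius, charge.
# Charges are in elementary-charge units, lengths in Angstrom.

ATOMSET_COLS <- c("serial", "name", "resname", "chain", "resno",
                  "x", "y", "z", "radius", "charge")

#' Construct an atom set
#'
#' An `atomset` is a data frame with one row per atom and columns
#' `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#' `radius` (Angstrom, > 0 for atoms used in surface computation) and
#' `charge` (elementary-charge units; 0 when the source format carries no
#' charges). Record order is preserved from the source.
#'
#' @param df data frame carrying the columns listed above.
#' @param source_label character label recording provenance (file path or
#'   fixture description).
#' @return An object of class `atomset`.
#' @export
atomset <- function(df, source_label = "") {
  missing_cols <- setdiff(ATOMSET_COLS, names(df))
  if (length(missing_cols) > 0)
    stop_zp("atomset is missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, ATOMSET_COLS]
  if (nrow(df) > 0) {
    bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
    if (any(bad))
      stop_zp("non-finite coordinates for atom(s): %s",
              paste(utils::head(which(bad), 5), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, source_label = source_label,
            class = c("atomset", "data.frame"))
}

#' @export
print.atomset <- function(x, ...) {
  cat(sprintf("atomset: %d atoms", nrow(x)))
  lab <- attr(x, "source_label")
  if (!is.null(lab) && nzchar(lab)) cat(sprintf(" [%s]", lab))
  cat("\n")
  if (nrow(x) > 0) {
    cat(sprintf("  residues %d-%d, chains: %s, net charge %.3f e\n",
                min(x$resno), max(x$resno),
                paste(unique(x$chain), collapse = ","), sum(x$charge)))
  }
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param atoms an `atomset`.
#' @return numeric n x 3 matrix of positions (Angstrom).
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Bundled van der Waals radius table
#'
#' Element-keyed van der Waals radii (Angstrom, Bondi-type values) used to
#' assign radii to atoms read from PDB files, which carry no radii of their
#' own. PQR files carry per-atom radii and do not use this table.
#'
#' @return Named numeric vector, names are upper-case element symbols.
#' @export
vdw_radii <- function() {
  c("H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
    "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98, "SE" = 1.90,
    "FE" = 1.80, "ZN" = 1.39, "MG" = 1.73, "CA" = 2.31, "NA" = 2.27,
    "K" = 2.75, "MN" = 1.97, "CU" = 1.40, "CO" = 1.80, "NI" = 1.63)
}

# Infer the element of a PDB atom from its record. `element_field` is
# columns 77-78 (authoritative when present); otherwise fall back on the
# atom-name field (columns 13-16): names starting in column 13 carry
# two-letter elements (FE, ZN, ...), names starting in column 14 are
# one-letter elements, a leading digit marks a hydrogen (1HB2 etc.).
infer_element <- function(raw_name, element_field, radius_table) {
  el <- toupper(trimws(element_field))
  if (nzchar(el)) return(el)
  nm <- toupper(raw_name)
  two <- trimws(substr(nm, 1, 2))
  if (grepl("^[0-9]", two)) return("H")
  if (substr(nm, 1, 1) != " " && nchar(two) == 2 &&
      two %in% names(radius_table) && !grepl("[A-Z]", substr(nm, 3, 4))) {
    # left-justified two-letter element name (e.g. "FE  ", "ZN  ")
    return(two)
  }
  first <- regmatches(nm, regexpr("[A-Z]", nm))
  if (length(first) == 0) return("")
  first
}

#' Read a PQR file
#'
#' Parses whitespace-delimited `ATOM`/`HETATM` records whose final two
#' fields are the per-atom partial charge (e) and radius (Angstrom), the
#' format produced by PDB2PQR. Record order is preserved. The optional
#' chain-identifier column is detected automatically.
#'
#' @param path path to a PQR file.
#' @return An [atomset()] with `charge` and `radius` populated.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop_zp("PQR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop_zp("no atoms in PQR file %s", path)
  idx <- which(rec)
  n <- length(idx)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    # record serial name resname [chain] resno x y z charge radius
    if (length(tok) < 10)
      stop_zp("PQR line %d: expected at least 10 fields, got %d", ln, length(tok))
    nt <- length(tok)
    charge <- suppressWarnings(as.numeric(tok[nt - 1]))
    radius <- suppressWarnings(as.numeric(tok[nt]))
    if (is.na(charge)) stop_zp("PQR line %d: non-numeric charge '%s'", ln, tok[nt - 1])
    if (is.na(radius)) stop_zp("PQR line %d: non-numeric radius '%s'", ln, tok[nt])
    if (radius <= 0) stop_zp("PQR line %d: radius must be > 0, got %g", ln, radius)
    xyz <- suppressWarnings(as.numeric(tok[(nt - 4):(nt - 2)]))
    if (anyNA(xyz)) stop_zp("PQR line %d: non-numeric coordinate field", ln)
    resno_tok <- tok[nt - 5]
    if (!grepl("^-?[0-9]+$", resno_tok)) {
      if (grepl("^-?[0-9]+[A-Za-z]$", resno_tok))
        stop_zp("PQR line %d: insertion codes are not supported ('%s')", ln, resno_tok)
      stop_zp("PQR line %d: non-integer residue number '%s'", ln, resno_tok)
    }
    chain <- if (nt >= 11) tok[5] else ""
    serial <- suppressWarnings(as.integer(tok[2]))
    if (is.na(serial)) stop_zp("PQR line %d: non-integer serial '%s'", ln, tok[2])
    out[[i]] <- data.frame(
      serial = serial, name = tok[3], resname = tok[4], chain = chain,
      resno = as.integer(resno_tok), x = xyz[1], y = xyz[2], z = xyz[3],
      radius = radius, charge = charge, stringsAsFactors = FALSE)
  }
  atomset(do.call(rbind, out), source_label = path)
}

parse_pdb_atom_line <- function(line, ln, radius_table) {
  raw_name <- substr(line, 13, 16)
  icode <- substr(line, 27, 27)
  if (icode != " " && nzchar(trimws(icode)))
    stop_zp("PDB line %d: insertion code '%s' is not supported", ln, icode)
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz))
    stop_zp("PDB line %d: malformed coordinate field", ln)
  resno <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
  if (is.na(resno))
    stop_zp("PDB line %d: malformed residue number field", ln)
  serial <- suppressWarnings(as.integer(trimws(substr(line, 7, 11))))
  if (is.na(serial)) serial <- ln
  el <- infer_element(raw_name, substr(line, 77, 78), radius_table)
  if (!el %in% names(radius_table))
    stop_zp("PDB line %d: element '%s' has no entry in the radius table", ln, el)
  data.frame(
    serial = serial, name = trimws(raw_name),
    resname = trimws(substr(line, 18, 20)),
    chain = trimws(substr(line, 22, 22)), resno = resno,
    x = xyz[1], y = xyz[2], z = xyz[3],
    radius = unname(radius_table[[el]]), charge = 0,
    stringsAsFactors = FALSE)
}

#' Read models from a (possibly multi-model) PDB file
#'
#' Fixed-column `ATOM`/`HETATM` records are parsed; `MODEL`/`ENDMDL`
#' delimiters split conformations. Radii are assigned from an element-keyed
#' table (PDB files carry none) and all partial charges are set to 0.
#'
#' @param path path to a PDB file.
#' @param radius_table named numeric vector mapping upper-case element
#'   symbols to radii in Angstrom; default [vdw_radii()].
#' @return A list of [atomset()] objects, one per model, in file order.
#' @export
read_pdb_models <- function(path, radius_table = vdw_radii()) {
  if (!file.exists(path)) stop_zp("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  current <- list()
  flush_model <- function() {
    if (length(current) == 0) return()
    df <- do.call(rbind, current)
    models[[length(models) + 1]] <<- atomset(
      df, source_label = sprintf("%s#model%d", path, length(models) + 1))
    current <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (tag == "ENDMDL") {
      flush_model()
    } else if (grepl("^(ATOM  |HETATM)", line)) {
      current[[length(current) + 1]] <- parse_pdb_atom_line(line, ln, radius_table)
    }
  }
  flush_model()
  if (length(models) == 0) stop_zp("no atoms in PDB file %s", path)
  models
}

#' Read one model from a PDB file
#'
#' @inheritParams read_pdb_models
#' @param model 1-based model index to return (default first).
#' @return An [atomset()]; partial charges are 0.
#' @export
read_pdb <- function(path, radius_table = vdw_radii(), model = 1) {
  models <- read_pdb_models(path, radius_table)
  if (model < 1 || model > length(models))
    stop_zp("model %d requested but file has %d model(s)", model, length(models))
  models[[model]]
}

#' Parse a residue-range selection string
#'
#' The syntax mirrors published binding-site definitions: semicolon-separated
#' inclusive integer ranges, e.g. `"252-257; 275-291; 339-362"` (en dash
#' accepted). A range may be prefixed with a chain id and colon
#' (`"A:10-20"`); without a prefix the range matches any chain.
#'
#' @param text selection string.
#' @return A `residue_selection`: data frame with columns `chain` (NA =
#'   wildcard), `start`, `end`.
#' @export
residue_selection <- function(text) {
  text <- gsub("–", "-", text)  # en dash -> hyphen
  parts <- trimws(strsplit(text, ";")[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop_zp("empty residue selection")
  rows <- lapply(parts, function(p) {
    chain <- NA_character_
    if (grepl(":", p, fixed = TRUE)) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      chain <- trimws(bits[1])
      p <- trimws(bits[2])
    }
    m <- regmatches(p, regexec("^(-?[0-9]+)\\s*-\\s*(-?[0-9]+)$", p))[[1]]
    if (length(m) == 3) {
      se <- as.integer(m[2:3])
    } else if (grepl("^-?[0-9]+$", p)) {
      se <- rep(as.integer(p), 2)
    } else {
      stop_zp("cannot parse residue range '%s'", p)
    }
    if (se[1] > se[2]) stop_zp("range start %d > end %d in '%s'", se[1], se[2], p)
    data.frame(chain = chain, start = se[1], end = se[2], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("residue_selection", "data.frame"))
}

#' Select the atoms of a patch by residue ranges
#'
#' Returns exactly the atoms whose (chain, residue number) falls in the
#' union of the selection's inclusive intervals; atom order is preserved.
#' A selection whose chain is NA matches any chain.
#'
#' @param atoms an [atomset()].
#' @param selection a `residue_selection` or a selection string (parsed with
#'   [residue_selection()]).
#' @return The selected [atomset()].
#' @export
select_patch <- function(atoms, selection) {
  if (is.character(selection)) selection <- residue_selection(selection)
  if (!inherits(selection, "residue_selection"))
    stop_zp("selection must be a residue_selection or string")
  keep <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(selection))) {
    hit <- atoms$resno >= selection$start[i] & atoms$resno <= selection$end[i]
    if (!is.na(selection$chain[i]))
      hit <- hit & atoms$chain == selection$chain[i]
    keep <- keep | hit
  }
  if (!any(keep)) stop_zp("selection matches no atoms")
  atomset(atoms[keep, , drop = FALSE],
          source_label = attr(atoms, "source_label") %||% "")
}
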