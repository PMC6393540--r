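## Minimal fixed-column PDB reading/writing and atom selections.
##
## Only the coordinate section is interpreted (ATOM/HETATM, MODEL/ENDMDL,
## TER). mmCIF is out of scope. No R PDB parser is available in the
## dependency set, and the format subset needed here is small enough that
## a careful fixed-column reader is the most transparent choice.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")
.WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' Read a structure from a PDB file
#'
#' Parses the coordinate records of one model of a PDB file into a
#' `structure_model`: a data.frame of atoms with chain, residue number and
#' insertion code, residue name, atom name, element, coordinates and
#' occupancy. Alternate locations other than the requested one are
#' dropped; waters are always excluded; HETATM records are excluded by
#' default.
#'
#' @param path PDB file path.
#' @param model_index which MODEL to keep when several are present
#'   (default 1; files without MODEL records are treated as one model).
#' @param altloc alternate-location policy: keep blank or this identifier
#'   (default `"A"`).
#' @param include_het include HETATM records (waters stay excluded).
#' @return Object of class `structure_model`: data.frame with columns
#'   `chain`, `resid`, `icode`, `resname`, `atom`, `element`, `x`, `y`,
#'   `z`, `occupancy`, `het`; attribute `source`.
#' @export
read_structure <- function(path, model_index = 1L, altloc = "A",
                           include_het = FALSE) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model <- cumsum(trimws(rec) == "MODEL")
  has_models <- any(model > 0L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop_domain("no ATOM/HETATM records in ", path)
  if (has_models) {
    keep_model <- model == model_index & is_atom
    if (!any(keep_model))
      stop_domain("model ", model_index, " not present in ", path)
    idx <- which(keep_model)
  } else {
    if (model_index != 1L) stop_domain("file has a single model")
    idx <- which(is_atom)
  }
  ln <- lines[idx]
  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    chain = substr(ln, 22L, 22L),
    resid = as.integer(num(substr(ln, 23L, 26L))),
    icode = trimws(substr(ln, 27L, 27L)),
    resname = trimws(substr(ln, 18L, 20L)),
    atom = trimws(substr(ln, 13L, 16L)),
    altloc = substr(ln, 17L, 17L),
    element = trimws(substr(ln, 77L, 78L)),
    x = num(substr(ln, 31L, 38L)),
    y = num(substr(ln, 39L, 46L)),
    z = num(substr(ln, 47L, 54L)),
    occupancy = num(substr(ln, 55L, 60L)),
    het = substr(ln, 1L, 6L) == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop_domain("unparseable coordinates in ", path)
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1
  ## element fallback from the atom name (first alphabetic character)
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[^A-Za-z].*", "",
                                      gsub("^[0-9]*", "", atoms$atom[blank])),
                                 1L, 1L)
  atoms <- atoms[atoms$altloc %in% c(" ", "", altloc), ]
  atoms <- atoms[!(atoms$resname %in% .WATER_RESNAMES), ]
  if (!include_het) atoms <- atoms[!atoms$het, ]
  atoms$altloc <- NULL
  if (nrow(atoms) == 0L) stop_domain("selection empty after filtering in ", path)
  rownames(atoms) <- NULL
  structure(atoms, class = c("structure_model", "data.frame"),
            source = path)
}

#' Write a structure to a PDB file
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  n <- nrow(model)
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(model$het, "HETATM", "ATOM"),
    seq_len(n) %% 100000L,
    ifelse(nchar(model$atom) < 4L, paste0(" ", model$atom), model$atom),
    model$resname, model$chain, model$resid,
    ifelse(model$icode == "", " ", model$icode),
    model$x, model$y, model$z, model$occupancy, 0,
    model$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Atom selection
#'
#' Selects atoms by chain, inclusive residue range(s) in author numbering,
#' and an atom-name set. The string form `"A:4-99:backbone"` (chain,
#' range, atom set) is also accepted by all metric functions; atom set
#' `"backbone"` means N, CA, C, O; `"CA"` only alpha carbons; `"all"`
#' (default) everything.
#'
#' @param chain chain identifier(s).
#' @param resid_range `NULL` (all residues), a length-2 vector, or a list
#'   of length-2 inclusive ranges.
#' @param atoms atom-name vector, or `"backbone"`, `"CA"`, `"all"`.
#' @return Object of class `atom_selection`.
#' @export
selection <- function(chain = NULL, resid_range = NULL, atoms = "all") {
  if (!is.null(resid_range) && !is.list(resid_range))
    resid_range <- list(resid_range)
  structure(list(chain = chain, resid_range = resid_range, atoms = atoms),
            class = "atom_selection")
}

#' Parse a selection string
#'
#' @param s string like `"A:4-99:backbone"`, `"A"`, or `"A:4-99"`.
#' @return An [selection()] object.
#' @export
parse_selection <- function(s) {
  if (inherits(s, "atom_selection")) return(s)
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  chain <- if (parts[1L] == "") NULL else strsplit(parts[1L], ",")[[1L]]
  rng <- NULL
  if (length(parts) >= 2L && nzchar(parts[2L])) {
    rng <- lapply(strsplit(parts[2L], ",")[[1L]], function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1L]])
      if (length(ab) == 1L) ab <- c(ab, ab)
      ab
    })
  }
  atoms <- if (length(parts) >= 3L && nzchar(parts[3L])) parts[3L] else "all"
  selection(chain = chain, resid_range = rng, atoms = atoms)
}

## Resolve a selection to atom row indices of a model.
resolve_selection <- function(model, sel) {
  sel <- parse_selection(sel)
  keep <- rep(TRUE, nrow(model))
  if (!is.null(sel$chain)) keep <- keep & model$chain %in% sel$chain
  if (!is.null(sel$resid_range)) {
    in_rng <- rep(FALSE, nrow(model))
    for (r in sel$resid_range)
      in_rng <- in_rng | (model$resid >= r[1L] & model$resid <= r[2L])
    keep <- keep & in_rng
  }
  atoms <- sel$atoms
  if (length(atoms) == 1L && atoms %in% c("backbone", "CA", "all")) {
    atoms <- switch(atoms, backbone = .BACKBONE_ATOMS, CA = "CA", all = NULL)
  }
  if (!is.null(atoms)) keep <- keep & model$atom %in% atoms
  idx <- which(keep)
  if (length(idx) == 0L) stop_domain("selection resolves to no atoms")
  idx
}

## Coordinate matrix of a selection.
selection_coords <- function(model, sel) {
  idx <- resolve_selection(model, sel)
  as.matrix(model[idx, c("x", "y", "z")])
}

#' Net formal side-chain charge of a protein sequence
#'
#' Counts +1 per Lys/Arg and -1 per Asp/Glu; His and the termini are
#' ignored (the conventional formal count for disorder-segment charge
#' bookkeeping).
#'
#' @param sequence one-letter amino-acid string.
#' @return Integer net charge.
#' @examples
#' sequence_net_charge("KRDEKRH")  # +2
#' @export
sequence_net_charge <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  bad <- setdiff(aa, valid)
  if (length(bad) > 0L)
    stop_domain("invalid one-letter code(s): ", paste(unique(bad), collapse = ", "))
  sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
}
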