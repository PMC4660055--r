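# Minimal PDB-format coordinate I/O. Only ATOM/HETATM records are
# read; alternate locations resolve to the first occurrence and
# insertion codes are rejected (renumber upstream if present).

#' Read ATOM/HETATM records from a PDB file
#'
#' @param input path to a PDB file, or character vector of lines.
#' @return data frame with `record`, `serial`, `atom_name`, `altloc`,
#'   `res_name`, `chain`, `res_seq`, `x`, `y`, `z`, `element`.
#' @export
read_pdb <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found", call. = FALSE)
  idx <- which(sel)
  fx <- function(ln, from, to) substr(ln, from, to)
  rows <- lapply(idx, function(i) {
    ln <- lines[i]
    icode <- trimws(fx(ln, 27, 27))
    if (nzchar(icode)) {
      stop("insertion code at line ", i, " not supported", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(fx(ln, 31, 38), fx(ln, 39, 46), fx(ln, 47, 54))))
    if (any(is.na(xyz))) stop("malformed coordinate field at line ", i, call. = FALSE)
    el <- trimws(fx(ln, 77, 78))
    nm <- trimws(fx(ln, 13, 16))
    if (!nzchar(el)) el <- substr(gsub("[0-9']", "", nm), 1, 1)
    data.frame(
      record = trimws(fx(ln, 1, 6)),
      serial = suppressWarnings(as.integer(fx(ln, 7, 11))),
      atom_name = nm, altloc = trimws(fx(ln, 17, 17)),
      res_name = trimws(fx(ln, 18, 20)), chain = trimws(fx(ln, 22, 22)),
      res_seq = suppressWarnings(as.integer(fx(ln, 23, 26))),
      x = xyz[1], y = xyz[2], z = xyz[3], element = el,
      stringsAsFactors = FALSE
    )
  })
  atoms <- do.call(rbind, rows)
  # altloc: keep the first conformer per (chain, residue, atom)
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write atoms as PDB ATOM records
#'
#' Coordinates are written at the standard three-decimal PDB
#' precision.
#'
#' @param atoms data frame as returned by [read_pdb()] (or with the
#'   same columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  nm <- atoms$atom_name
  # standard alignment: element starts in column 14 for short names
  nm_fmt <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), nm_fmt, atoms$res_name, atoms$chain, atoms$res_seq,
    atoms$x, atoms$y, atoms$z, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
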