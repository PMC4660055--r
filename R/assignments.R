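# Assignment model: every observed resonance is tied to a residue
# (1-based numbering of the modelled 1-219 construct) and a probe group
# (backbone amide, or one of the Ile/Leu/Val methyls used by
# methyl-TROSY experiments).

.methyl_atoms <- list(
  I = c("CD1"),
  L = c("CD1", "CD2"),
  V = c("CG1", "CG2")
)

#' Parse a Sparky-style assignment token
#'
#' Tokens look like `"V136N-H"` (backbone amide of Val136) or
#' `"L140CD1-QD1"` (Leu140 delta1 methyl). A trailing `_a` or `_b`
#' marks one of two resolved peak variants for residues that show
#' doubled resonances in the DNA-bound state.
#'
#' @param token character scalar.
#' @return list with `residue_type`, `residue_index`, `atom_x`,
#'   `atom_h`, `group` (one of `amide`, `ile_delta1`, `leu_methyl`,
#'   `val_methyl`), `variant` (`"a"` or `"b"`) and `key` (canonical
#'   assignment string without the variant suffix).
#' @export
parse_assignment <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  variant <- "a"
  if (grepl("_(a|b)$", tok)) {
    variant <- sub("^.*_", "", tok)
    tok <- sub("_(a|b)$", "", tok)
  }
  m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z0-9']+)-([A-Z0-9']+)$", tok))[[1]]
  if (length(m) == 0L) {
    stop("unparseable assignment token: '", token, "'", call. = FALSE)
  }
  res_type <- m[2]
  res_idx <- as.integer(m[3])
  atom_x <- m[4]
  atom_h <- m[5]
  if (res_idx < 1L) stop("residue index must be >= 1 in '", token, "'", call. = FALSE)
  group <- NULL
  if (atom_x == "N") {
    group <- "amide"
  } else if (res_type %in% names(.methyl_atoms) &&
             atom_x %in% .methyl_atoms[[res_type]]) {
    group <- switch(res_type, I = "ile_delta1", L = "leu_methyl", V = "val_methyl")
  } else {
    stop("atom '", atom_x, "' is not an amide N or an Ile/Leu/Val methyl carbon in '",
         token, "'", call. = FALSE)
  }
  list(
    residue_type = res_type, residue_index = res_idx,
    atom_x = atom_x, atom_h = atom_h, group = group,
    variant = variant,
    key = paste0(res_type, res_idx, atom_x, "-", atom_h)
  )
}

#' Domain map of the response-regulator construct
#'
#' Named residue ranges partitioning the construct into the receiver
#' domain (REC), the interdomain linker and the DNA-binding domain
#' (DBD). `DBD_stat` is the DBD range used for domain statistics,
#' excluding the C-terminal seven residues whose high flexibility
#' would bias means.
#'
#' @param rec,linker,dbd,dbd_stat integer vectors of residue indices.
#' @return object of class `domain_map` (named list of index vectors).
#' @export
domain_map <- function(rec = 1:116, linker = 117:125, dbd = 126:219,
                       dbd_stat = 126:212) {
  dm <- list(REC = as.integer(rec), linker = as.integer(linker),
             DBD = as.integer(dbd), DBD_stat = as.integer(dbd_stat))
  if (length(intersect(dm$REC, dm$linker)) || length(intersect(dm$REC, dm$DBD)) ||
      length(intersect(dm$linker, dm$DBD))) {
    stop("REC, linker and DBD ranges must be disjoint", call. = FALSE)
  }
  if (!all(dm$DBD_stat %in% dm$DBD)) {
    stop("DBD_stat must be a subset of DBD", call. = FALSE)
  }
  structure(dm, class = "domain_map")
}

#' Default domain map (REC 1-116, linker 117-125, DBD 126-219,
#' statistics over DBD 126-212)
#' @return a `domain_map`.
#' @export
default_domain_map <- function() domain_map()

#' Assign residues to domains
#' @param residue_index integer vector.
#' @param dm a `domain_map`.
#' @param stat use the statistics ranges (`DBD_stat` instead of `DBD`).
#' @return character vector (`"REC"`, `"linker"`, `"DBD"` or `NA`).
#' @export
domain_of <- function(residue_index, dm = default_domain_map(), stat = FALSE) {
  dbd <- if (stat) dm$DBD_stat else dm$DBD
  out <- rep(NA_character_, length(residue_index))
  out[residue_index %in% dm$REC] <- "REC"
  out[residue_index %in% dm$linker] <- "linker"
  out[residue_index %in% dbd] <- "DBD"
  out
}
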