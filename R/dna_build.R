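# Nucleic duplex container and the ideal B-DNA builder. A duplex is a
# table of atoms labelled by strand (1 or 2) and pair index; strand 2
# runs antiparallel, so its 5'->3' residue order is the reverse of the
# pair index.

.rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

.rot_axis <- function(u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Kabsch superposition: rotation R and translation t minimising
# ||Q - (P R' + t)||; returns the proper rotation (det +1).
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

.new_duplex <- function(atoms, sequence) {
  structure(list(atoms = atoms, sequence = sequence,
                 n_pairs = length(sequence)),
            class = "nucleic_duplex")
}

#' @export
print.nucleic_duplex <- function(x, ...) {
  cat(sprintf("nucleic duplex: %d base pairs, %d atoms\n  strand 1: 5'-%s-3'\n",
              x$n_pairs, nrow(x$atoms), paste(x$sequence, collapse = "")))
  invisible(x)
}

#' Build an ideal B-form DNA duplex
#'
#' Stacks standard base-pair geometries along a straight helix axis
#' with uniform rise and twist. The complementary strand is generated
#' antiparallel by the pair dyad. Backbone phosphates are placed at a
#' fixed radius/azimuth relative to each pair frame (5'-terminal
#' residues carry no phosphate, as in real structures).
#'
#' @param sequence character string or vector over A/C/G/T (length >= 2),
#'   5'->3' of strand 1.
#' @param rise helical rise per step (Angstrom).
#' @param twist helical twist per step (degrees).
#' @param p_azimuth_deg azimuth of the phosphate relative to the pair
#'   frame; the default reproduces the canonical ~12 A raw minor
#'   groove. Smaller values narrow the minor groove.
#' @return a `nucleic_duplex`.
#' @export
build_ideal_bdna <- function(sequence, rise = 3.32, twist = 36.0,
                             p_azimuth_deg = .phosphate_geometry[["azimuth_deg"]]) {
  seq1 <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  seq1 <- toupper(seq1)
  if (length(seq1) < 2L) stop("sequence must have >= 2 bases", call. = FALSE)
  if (!all(seq1 %in% names(.complement))) {
    stop("invalid base(s): ", paste(setdiff(seq1, names(.complement)), collapse = ","),
         call. = FALSE)
  }
  n <- length(seq1)
  flip <- diag(c(1, -1, -1))  # pair dyad about x: maps strand-1 frame to strand-2
  rP <- .phosphate_geometry[["radius"]]
  zP <- .phosphate_geometry[["z_offset"]]
  phiP <- p_azimuth_deg * pi / 180
  p1_local <- c(rP * cos(phiP), rP * sin(phiP), zP)
  p2_local <- as.numeric(flip %*% p1_local)

  rows <- list()
  for (i in seq_len(n)) {
    Rz <- .rotz((i - 1) * twist)
    shift <- c(0, 0, (i - 1) * rise)
    place <- function(v) as.numeric(Rz %*% v) + shift
    b1 <- seq1[i]
    b2 <- .complement[[b1]]
    t1 <- .base_templates[[b1]]
    t2 <- .base_templates[[b2]]
    for (a in rownames(t1)) {
      xyz <- place(t1[a, ])
      rows[[length(rows) + 1L]] <- data.frame(
        strand = 1L, pair = i, res_name = b1, atom_name = a,
        x = xyz[1], y = xyz[2], z = xyz[3],
        element = substr(gsub("[0-9']", "", a), 1, 1), stringsAsFactors = FALSE)
    }
    for (a in rownames(t2)) {
      xyz <- place(as.numeric(flip %*% t2[a, ]))
      rows[[length(rows) + 1L]] <- data.frame(
        strand = 2L, pair = i, res_name = b2, atom_name = a,
        x = xyz[1], y = xyz[2], z = xyz[3],
        element = substr(gsub("[0-9']", "", a), 1, 1), stringsAsFactors = FALSE)
    }
    if (i > 1L) {  # strand 1 runs 5'->3' with the pair index
      xyz <- place(p1_local)
      rows[[length(rows) + 1L]] <- data.frame(
        strand = 1L, pair = i, res_name = b1, atom_name = "P",
        x = xyz[1], y = xyz[2], z = xyz[3], element = "P",
        stringsAsFactors = FALSE)
    }
    if (i < n) {   # strand 2 runs 5'->3' against the pair index
      xyz <- place(p2_local)
      rows[[length(rows) + 1L]] <- data.frame(
        strand = 2L, pair = i, res_name = b2, atom_name = "P",
        x = xyz[1], y = xyz[2], z = xyz[3], element = "P",
        stringsAsFactors = FALSE)
    }
  }
  .new_duplex(do.call(rbind, rows), seq1)
}

#' Apply a rigid-body motion to a duplex
#' @param duplex a `nucleic_duplex`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector.
#' @return transformed `nucleic_duplex`.
#' @export
transform_duplex <- function(duplex, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(duplex$atoms[, c("x", "y", "z")]) %*% t(R)
  duplex$atoms$x <- xyz[, 1] + t[1]
  duplex$atoms$y <- xyz[, 2] + t[2]
  duplex$atoms$z <- xyz[, 3] + t[3]
  duplex
}

#' Bend a duplex at a chosen step
#'
#' Rotates all pairs after `split` rigidly about an axis perpendicular
#' to the helix axis through the junction midpoint, producing two
#' straight arms whose axes differ by `angle_deg`. Used to emulate
#' gently curved protein-bound DNA.
#'
#' @param duplex a straight `nucleic_duplex` from [build_ideal_bdna()].
#' @param split pair index ending the first arm.
#' @param angle_deg bend angle between the two arm axes (degrees).
#' @return bent `nucleic_duplex`.
#' @export
bend_duplex <- function(duplex, split, angle_deg) {
  stopifnot(split >= 1, split < duplex$n_pairs)
  atoms <- duplex$atoms
  sel <- atoms$pair > split
  # junction on the helix axis between the two arms (builder axis = z)
  rise <- diff(range(atoms$z[atoms$atom_name != "P"])) / (duplex$n_pairs - 1)
  pivot <- c(0, 0, (split - 0.5) * rise)
  R <- .rot_axis(c(1, 0, 0), angle_deg)
  xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, `+`)
  atoms[sel, c("x", "y", "z")] <- xyz
  duplex$atoms <- atoms
  duplex
}

#' Convert a duplex to a PDB-style atom table
#'
#' Strand 1 becomes chain `C` numbered with the pair index; strand 2
#' chain `D` numbered 5'->3' (reverse of the pair index). Residue
#' names use the DNA convention (DA/DC/DG/DT).
#'
#' @param duplex a `nucleic_duplex`.
#' @return atom data frame compatible with [write_pdb()].
#' @export
duplex_to_atoms <- function(duplex) {
  a <- duplex$atoms
  n <- duplex$n_pairs
  data.frame(
    record = "ATOM", serial = seq_len(nrow(a)), atom_name = a$atom_name,
    altloc = "", res_name = paste0("D", a$res_name),
    chain = ifelse(a$strand == 1L, "C", "D"),
    res_seq = ifelse(a$strand == 1L, a$pair, n + 1L - a$pair),
    x = a$x, y = a$y, z = a$z, element = a$element,
    stringsAsFactors = FALSE
  )
}

#' Extract a nucleic duplex from a PDB atom table
#'
#' The two chains are paired antiparallel: the i-th residue of the
#' first chain (in residue-number order) pairs with the i-th-from-last
#' residue of the second. Pairs that are not Watson-Crick
#' complementary trigger a warning, not an error.
#'
#' @param atoms data frame from [read_pdb()].
#' @param chains length-2 character vector of chain identifiers
#'   (strand 1, strand 2).
#' @return a `nucleic_duplex`.
#' @export
duplex_from_atoms <- function(atoms, chains = c("C", "D")) {
  s1 <- atoms[atoms$chain == chains[1], , drop = FALSE]
  s2 <- atoms[atoms$chain == chains[2], , drop = FALSE]
  if (nrow(s1) == 0L || nrow(s2) == 0L) {
    stop("chain(s) not found: ", paste(chains, collapse = ","), call. = FALSE)
  }
  r1 <- sort(unique(s1$res_seq))
  r2 <- sort(unique(s2$res_seq), decreasing = TRUE)  # antiparallel
  n <- min(length(r1), length(r2))
  rows <- list()
  seq1 <- character(n)
  for (i in seq_len(n)) {
    for (k in 1:2) {
      src <- if (k == 1) s1 else s2
      res <- if (k == 1) r1[i] else r2[i]
      sub <- src[src$res_seq == res, , drop = FALSE]
      base <- .pdb_base(sub$res_name[1])
      if (k == 1) seq1[i] <- base
      if (is.na(base)) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = k, pair = i, res_name = base, atom_name = sub$atom_name,
        x = sub$x, y = sub$y, z = sub$z, element = sub$element,
        stringsAsFactors = FALSE)
    }
  }
  dup <- .new_duplex(do.call(rbind, rows), seq1)
  a <- dup$atoms
  for (i in seq_len(n)) {
    b1 <- unique(a$res_name[a$pair == i & a$strand == 1L])
    b2 <- unique(a$res_name[a$pair == i & a$strand == 2L])
    if (length(b1) && length(b2) && !identical(.complement[[b1]], b2)) {
      warning("pair ", i, " (", b1, "-", b2, ") is not Watson-Crick complementary")
    }
  }
  dup
}
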