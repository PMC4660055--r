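# Shrake-Rupley solvent-accessible surface area and buried interface
# area between two atom sets.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

# deterministic near-uniform sphere sampling (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is sampled with `n_points` near-uniform points on its
#' solvent-expanded sphere (van der Waals radius + probe); points
#' falling inside any neighbour's expanded sphere are buried.
#'
#' @param atoms data frame with `x`, `y`, `z`, `element` (C/N/O/P/S/H).
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points sphere sample points per atom (>= 960 recommended).
#' @return total SASA in Angstrom^2; per-atom values in the
#'   `per_atom` attribute.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  unknown <- setdiff(unique(atoms$element), names(.vdw_radii))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .vdw_radii[atoms$element] + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(di < r[i] + r & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 >= r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  structure(sum(areas), per_atom = areas)
}

#' Buried interface area between two atom sets
#'
#' \eqn{(SASA(A) + SASA(B) - SASA(A \cup B)) / 2}; symmetric and
#' non-negative.
#'
#' @param atoms_a,atoms_b disjoint atom data frames (see [sasa()]).
#' @param probe probe radius (Angstrom).
#' @param n_points sphere sample points per atom.
#' @return buried area in Angstrom^2.
#' @export
buried_interface_area <- function(atoms_a, atoms_b, probe = 1.4, n_points = 960) {
  cols <- c("x", "y", "z", "element")
  both <- rbind(atoms_a[, cols], atoms_b[, cols])
  max((as.numeric(sasa(atoms_a, probe, n_points)) +
         as.numeric(sasa(atoms_b, probe, n_points)) -
         as.numeric(sasa(both, probe, n_points))) / 2, 0)
}
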