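# Duplex geometry: base-pair reference frames by least-squares
# template superposition, mid-step twist/rise, raw cross-strand P-P
# minor-groove widths, and the two-arm global bend angle.

# nearest proper rotation to M (polar decomposition)
.orthonormalize <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

.axis_angle <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-10) return(list(axis = c(0, 0, 1), angle = 0))
  u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(u^2)) < 1e-10) {  # 180-degree rotation
    ev <- eigen(R)
    u <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  }
  list(axis = u / sqrt(sum(u^2)), angle = ang * 180 / pi)
}

#' Base-pair reference frames of a duplex
#'
#' For each pair, the standard base geometry is superposed onto the
#' observed base ring atoms of both strands (least squares); the
#' strand-2 frame is flipped about its x-axis into the strand-1
#' convention and the pair frame is the orthonormalized average of the
#' two, with origin at the midpoint. Pairs with fewer than three ring
#' atoms on either base are skipped with a warning.
#'
#' @param duplex a `nucleic_duplex`.
#' @return list of frames; each has `origin` (length 3) and `axes`
#'   (3x3 matrix, columns x/y/z, right-handed orthonormal) plus the
#'   `pair` index.
#' @export
base_pair_frames <- function(duplex) {
  a <- duplex$atoms
  frames <- list()
  for (i in seq_len(duplex$n_pairs)) {
    fr <- vector("list", 2)
    ok <- TRUE
    for (k in 1:2) {
      sub <- a[a$pair == i & a$strand == k, , drop = FALSE]
      if (nrow(sub) == 0L) { ok <- FALSE; break }
      base <- sub$res_name[1]
      ring <- intersect(.base_ring_atoms[[base]], sub$atom_name)
      if (length(ring) < 3L) { ok <- FALSE; break }
      tpl <- .base_templates[[base]][ring, , drop = FALSE]
      obs <- as.matrix(sub[match(ring, sub$atom_name), c("x", "y", "z")])
      fit <- .kabsch(tpl, obs)
      ax <- fit$R
      if (k == 2) ax <- ax %*% diag(c(1, -1, -1))  # into strand-1 convention
      fr[[k]] <- list(origin = fit$t, axes = ax)
    }
    if (!ok) {
      warning("pair ", i, " skipped: missing base ring atoms")
      next
    }
    axes <- .orthonormalize((fr[[1]]$axes + fr[[2]]$axes) / 2)
    frames[[length(frames) + 1L]] <- list(
      pair = i, origin = (fr[[1]]$origin + fr[[2]]$origin) / 2, axes = axes)
  }
  frames
}

#' Base-pair step parameters (twist and rise)
#'
#' Mid-step triad convention: for consecutive frames the half-way
#' rotation defines a mid-step frame; rise is the origin displacement
#' along its z-axis and twist the signed angle between the two x-axes
#' projected onto the plane normal to it.
#'
#' @param frames output of [base_pair_frames()] (>= 2 frames).
#' @return data frame (`step`, `twist`, `rise`) with attributes
#'   `mean_twist`, `mean_rise`, `sd_twist`, `sd_rise`.
#' @export
step_parameters <- function(frames) {
  if (length(frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  out <- data.frame(step = integer(), twist = numeric(), rise = numeric())
  for (i in seq_len(length(frames) - 1L)) {
    f1 <- frames[[i]]
    f2 <- frames[[i + 1L]]
    A <- t(f1$axes) %*% f2$axes
    aa <- .axis_angle(A)
    H <- .rot_axis(aa$axis, aa$angle / 2)
    Rm <- f1$axes %*% H
    zm <- Rm[, 3]
    rise <- sum((f2$origin - f1$origin) * zm)
    proj <- function(v) { w <- v - sum(v * zm) * zm; w / sqrt(sum(w^2)) }
    x1 <- proj(f1$axes[, 1])
    x2 <- proj(f2$axes[, 1])
    tw <- atan2(sum(zm * c(
      x1[2] * x2[3] - x1[3] * x2[2],
      x1[3] * x2[1] - x1[1] * x2[3],
      x1[1] * x2[2] - x1[2] * x2[1])), sum(x1 * x2)) * 180 / pi
    out <- rbind(out, data.frame(step = i, twist = tw, rise = rise))
  }
  attr(out, "mean_twist") <- mean(out$twist)
  attr(out, "mean_rise") <- mean(out$rise)
  attr(out, "sd_twist") <- stats::sd(out$twist)
  attr(out, "sd_rise") <- stats::sd(out$rise)
  out
}

#' Minor-groove width profile
#'
#' Raw cross-strand phosphate-phosphate distances (no van der Waals
#' subtraction): at each strand-1 phosphate position the width is the
#' minimum distance to any strand-2 phosphate within `window` pairs.
#' On canonical B-DNA built by [build_ideal_bdna()] this convention
#' reads about 11.6 A.
#'
#' @param duplex a `nucleic_duplex` with phosphate atoms.
#' @param window half-width of the cross-strand search window (pairs).
#' @return data frame (`position`, `width`); positions lacking
#'   phosphates on either side are skipped.
#' @export
minor_groove_widths <- function(duplex, window = 6L) {
  a <- duplex$atoms
  p1 <- a[a$strand == 1L & a$atom_name == "P", , drop = FALSE]
  p2 <- a[a$strand == 2L & a$atom_name == "P", , drop = FALSE]
  if (nrow(p1) == 0L || nrow(p2) == 0L) stop("no phosphate atoms", call. = FALSE)
  out <- data.frame(position = integer(), width = numeric())
  for (i in seq_len(nrow(p1))) {
    # terminal positions with a truncated cross-strand window have no
    # defined groove width
    if (p1$pair[i] - window < min(p2$pair) || p1$pair[i] + window > max(p2$pair)) next
    sel <- abs(p2$pair - p1$pair[i]) <= window
    if (!any(sel)) next
    d <- sqrt((p2$x[sel] - p1$x[i])^2 + (p2$y[sel] - p1$y[i])^2 +
                (p2$z[sel] - p1$z[i])^2)
    out <- rbind(out, data.frame(position = p1$pair[i], width = min(d)))
  }
  out
}

#' Global bend angle between two duplex arms
#'
#' Fits a straight axis (first principal component of the frame
#' origins) to the pairs up to `split` and to the rest, and returns
#' the angle between the two axes, each oriented along the 5'->3'
#' progression.
#'
#' @param frames output of [base_pair_frames()].
#' @param split pair index ending the first arm (default midpoint).
#' @return bend angle in degrees, in [0, 180].
#' @export
bend_angle <- function(frames, split = NULL) {
  orig <- t(vapply(frames, `[[`, numeric(3), "origin"))
  n <- nrow(orig)
  if (is.null(split)) split <- floor(n / 2)
  idx1 <- seq_len(split)
  idx2 <- (split + 1L):n
  if (length(idx1) < 4L || length(idx2) < 4L) {
    stop("need >= 4 frames per segment", call. = FALSE)
  }
  axis_of <- function(idx) {
    X <- sweep(orig[idx, , drop = FALSE], 2, colMeans(orig[idx, , drop = FALSE]))
    v <- svd(X)$v[, 1]
    dir <- orig[idx[length(idx)], ] - orig[idx[1], ]
    if (sum(v * dir) < 0) v <- -v
    v
  }
  v1 <- axis_of(idx1)
  v2 <- axis_of(idx2)
  acos(pmin(pmax(sum(v1 * v2), -1), 1)) * 180 / pi
}
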