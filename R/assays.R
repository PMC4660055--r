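# Binding and reporter assays: one-site fluorescence-polarization
# titration fits (exact ligand-depletion solution) and Miller-unit
# conversion for the beta-galactosidase reporter.

#' Fraction of labelled DNA bound at a given protein concentration
#'
#' Exact one-site solution with ligand depletion:
#' \deqn{\theta = \frac{(P + D + K_d) - \sqrt{(P + D + K_d)^2 - 4 P D}}{2 D}}
#' With `dna_total = 0` the depletion-free hyperbola
#' \eqn{P/(K_d + P)} is returned.
#'
#' @param protein_total total protein concentration (nM, >= 0).
#' @param kd dissociation constant (nM, > 0).
#' @param dna_total total labelled DNA concentration (nM, default 6).
#' @return bound fraction in [0, 1].
#' @export
fraction_bound <- function(protein_total, kd, dna_total = 6) {
  stopifnot(all(protein_total >= 0), kd > 0, dna_total >= 0)
  if (dna_total == 0) return(protein_total / (kd + protein_total))
  s <- protein_total + dna_total + kd
  disc <- s^2 - 4 * protein_total * dna_total
  theta <- (s - sqrt(pmax(disc, 0))) / (2 * dna_total)
  pmin(pmax(theta, 0), 1)
}

#' Fit a one-site fluorescence-polarization titration
#'
#' Weighted least-squares fit of
#' \eqn{P(c) = p_{free} + (p_{bound} - p_{free})\,\theta(c; K_d, D)}
#' over all replicate points, using the exact depletion model for the
#' bound fraction. A grid that never reaches half-saturation leaves
#' Kd poorly determined and triggers a warning.
#'
#' @param points data frame with `protein_nM`, `polarization_mP`,
#'   `replicate` (>= 5 distinct concentrations).
#' @param dna_total labelled DNA concentration (nM).
#' @return list of class `binding_fit`: `kd`, `kd_error` (covariance),
#'   `p_free`, `p_bound`, `chi2`.
#' @export
fit_fp_titration <- function(points, dna_total = 6) {
  conc <- points$protein_nM
  pol <- points$polarization_mP
  if (length(unique(conc)) < 5L) {
    stop("need >= 5 distinct protein concentrations", call. = FALSE)
  }
  p_free0 <- mean(pol[conc == min(conc)])
  p_bound0 <- mean(pol[conc == max(conc)])
  kd0 <- stats::median(conc)
  res_fn <- function(p) {
    pol - (p[2] + (p[3] - p[2]) * fraction_bound(conc, p[1], dna_total))
  }
  fit <- minpack.lm::nls.lm(
    par = c(kd = kd0, p_free = p_free0, p_bound = p_bound0),
    lower = c(1e-6, -Inf, -Inf), upper = c(Inf, Inf, Inf),
    fn = res_fn, control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  if (max(fraction_bound(conc, p[[1]], dna_total)) < 0.5) {
    warning("titration never reaches half-saturation: Kd poorly determined")
  }
  cov <- .lm_cov(res_fn, p)
  se <- sqrt(pmax(diag(cov), 0))
  # scale covariance errors by reduced chi2 (unit-weight residuals)
  dof <- length(pol) - 3L
  s2 <- if (dof > 0) sum(fit$fvec^2) / dof else 1
  structure(list(kd = p[[1]], kd_error = se[1] * sqrt(s2),
                 p_free = p[[2]], p_bound = p[[3]],
                 chi2 = sum(fit$fvec^2)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("one-site binding fit: Kd = %.1f +/- %.1f nM (mP %.1f -> %.1f)\n",
              x$kd, x$kd_error, x$p_free, x$p_bound))
  invisible(x)
}

#' Beta-galactosidase activity in Miller units
#'
#' \eqn{1000 \times A_{420} / (T \times V \times A_{600})} with the
#' reaction time in minutes and culture volume in millilitres.
#'
#' @param abs420 absorbance at 420 nm (>= 0).
#' @param time_min reaction time in minutes (> 0).
#' @param volume_ml culture volume in millilitres (> 0).
#' @param a600 culture density at 600 nm (> 0).
#' @return Miller units.
#' @export
miller_units <- function(abs420, time_min, volume_ml, a600) {
  if (any(time_min <= 0) || any(volume_ml <= 0) || any(a600 <= 0)) {
    stop("time, volume and A600 must all be positive", call. = FALSE)
  }
  1000 * abs420 / (time_min * volume_ml * a600)
}
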