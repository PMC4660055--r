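# R1/R2 relaxation analysis: mono-exponential R2 decays, three-
# parameter R1 inversion recovery, R2/R1 domain statistics, the
# single-field rotational-correlation-time estimate, and bound/free
# peak intensity ratios.

#' Default inversion-recovery delay schedule for R1 (seconds)
#' @return numeric vector of 11 delays.
#' @export
r1_delays <- function() {
  c(10, 20, 40, 70, 120, 200, 300, 500, 700, 1000, 1500) / 1000
}

#' Default relaxation durations for R2 (seconds)
#' @return numeric vector of 8 durations.
#' @export
r2_delays <- function() {
  c(17.2, 34.3, 51.5, 68.6, 85.8, 102.9, 120.1, 137.2) / 1000
}

.rate_fit <- function(rate, amplitude, offset, rate_error, chi2, fit) {
  structure(list(rate = rate, amplitude = amplitude, offset = offset,
                 rate_error = rate_error, chi2 = chi2, fit = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate fit: rate = %.4g +/- %.2g s^-1, chi2 = %.4g\n",
              x$rate, x$rate_error, x$chi2))
  invisible(x)
}

#' Fit a mono-exponential R2 decay
#'
#' Least-squares fit of \eqn{I(t) = A e^{-R_2 t}}. Duplicate points at
#' the same delay are fitted jointly, preserving their scatter in the
#' residuals.
#'
#' @param delays delay times in seconds (>= 3 distinct values).
#' @param intensities peak intensities, same length.
#' @return a `rate_fit` (rate, amplitude, rate_error from the
#'   covariance matrix, chi2 = residual sum of squares).
#' @export
fit_r2_decay <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  if (length(unique(delays)) < 3L) stop("need >= 3 distinct delays", call. = FALSE)
  if (stats::sd(intensities) == 0) {
    stop("all intensities equal: decay rate unidentifiable", call. = FALSE)
  }
  pos <- intensities > 0
  cf <- stats::coef(stats::lm(log(intensities[pos]) ~ delays[pos]))
  start <- c(A = exp(cf[[1]]), R = max(-cf[[2]], 1e-3))
  res_fn <- function(p) intensities - p[1] * exp(-p[2] * delays)
  fit <- minpack.lm::nls.lm(par = start, fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) {
    stop("R2 fit did not converge (start A=", signif(start[1], 3),
         ", R=", signif(start[2], 3), "; n=", length(delays), ")", call. = FALSE)
  }
  p <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  .rate_fit(rate = p[[2]], amplitude = p[[1]], offset = NULL,
            rate_error = se[2], chi2 = sum(res_fn(p)^2), fit = fit)
}

#' Fit a three-parameter R1 inversion recovery
#'
#' Least-squares fit of
#' \eqn{I(t) = I_\infty - (I_\infty - I_0) e^{-R_1 t}}. A series whose
#' intensities are not on average recovering (increasing) triggers a
#' warning but the fit is still attempted.
#'
#' @param delays recovery delays in seconds (>= 4 distinct values).
#' @param intensities peak intensities.
#' @return a `rate_fit`; `amplitude` is \eqn{I_\infty}, `offset` is
#'   \eqn{I_0}.
#' @export
fit_r1_recovery <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  if (length(unique(delays)) < 4L) stop("need >= 4 distinct delays", call. = FALSE)
  ord <- order(delays)
  if (stats::cor(delays, intensities) < 0) {
    warning("R1 series is not recovering (intensity decreases with delay)")
  }
  Iinf0 <- intensities[ord][length(intensities)]
  I00 <- intensities[ord][1]
  start <- c(Iinf = Iinf0, I0 = I00, R = 1 / max(stats::median(delays), 1e-6))
  res_fn <- function(p) intensities - (p[1] - (p[1] - p[2]) * exp(-p[3] * delays))
  fit <- minpack.lm::nls.lm(par = start, fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9)) {
    stop("R1 fit did not converge (start R=", signif(start[3], 3),
         "; n=", length(delays), ")", call. = FALSE)
  }
  p <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  .rate_fit(rate = p[[3]], amplitude = p[[1]], offset = p[[2]],
            rate_error = se[3], chi2 = sum(res_fn(p)^2), fit = fit)
}

#' Rotational correlation time from an R2/R1 ratio
#'
#' Single-field estimate
#' \eqn{\tau_c = \sqrt{6 R_2/R_1 - 7} / (4\pi\nu_N)}, with
#' \eqn{\nu_N} the 15N Larmor frequency at the given spectrometer
#' field. Valid for a rigid isotropic tumbler with slow tumbling; the
#' ratio must exceed 7/6 for a real result.
#'
#' @param ratio R2/R1 (dimensionless, > 7/6; exactly 7/6 gives 0).
#' @param field_mhz 1H spectrometer frequency in MHz.
#' @return correlation time in nanoseconds.
#' @export
tau_c_from_r2r1 <- function(ratio, field_mhz) {
  if (any(ratio < 7 / 6)) {
    stop("R2/R1 below 7/6 gives an imaginary correlation time", call. = FALSE)
  }
  nu_n <- larmor_hz(field_mhz, "N")
  sqrt(6 * ratio - 7) / (4 * pi * nu_n) * 1e9
}

#' Per-domain R2/R1 statistics
#'
#' @param rates data frame with columns `residue_index`, `r1`, `r2`
#'   (one row per residue; residues missing either rate are excluded
#'   and listed in the `excluded` attribute).
#' @param dm a `domain_map`; statistics use REC and the `DBD_stat`
#'   range.
#' @return data frame with `domain`, `mean`, `sd`, `n` (sd is 0 with
#'   an `n1` flag when a domain holds a single residue).
#' @export
domain_r2r1 <- function(rates, dm = default_domain_map()) {
  ok <- is.finite(rates$r1) & is.finite(rates$r2)
  excl <- rates$residue_index[!ok]
  rates <- rates[ok, , drop = FALSE]
  rates$ratio <- rates$r2 / rates$r1
  rates$domain <- domain_of(rates$residue_index, dm, stat = TRUE)
  out <- lapply(c("REC", "DBD"), function(dn) {
    x <- rates$ratio[!is.na(rates$domain) & rates$domain == dn]
    if (length(x) == 0L) stop("no residues with both rates in domain ", dn, call. = FALSE)
    data.frame(domain = dn, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n = length(x), n1 = length(x) == 1L)
  })
  out <- do.call(rbind, out)
  attr(out, "excluded") <- excl
  out
}

#' Bound/free peak intensity ratios with domain statistics
#'
#' Ratios \eqn{I_{bound}/I_{free}} per assignment; doubled bound peaks
#' contribute their summed intensity. When a noise floor is supplied,
#' each ratio gets a quadrature-propagated error
#' \eqn{r\sqrt{(\sigma/I_b)^2 + (\sigma/I_f)^2}}. Domain means are
#' taken over REC and the DBD statistics range.
#'
#' @param bound,free `peak_list` objects (amide peaks).
#' @param dm a `domain_map`.
#' @param noise_floor optional absolute noise level of the spectra.
#' @return list with `ratios` (per-assignment data frame) and `stats`
#'   (per-domain mean/sd/n).
#' @export
intensity_ratios <- function(bound, free, dm = default_domain_map(),
                             noise_floor = NULL) {
  fr <- free[free$variant == "a", , drop = FALSE]
  rows <- lapply(unique(fr$key), function(k) {
    f <- fr[fr$key == k, , drop = FALSE]
    b <- bound[bound$key == k, , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    if (f$intensity == 0) {
      warning("zero free intensity for ", k, "; skipped")
      return(NULL)
    }
    ib <- sum(b$intensity)
    r <- ib / f$intensity
    err <- if (!is.null(noise_floor)) {
      r * sqrt((noise_floor / ib)^2 + (noise_floor / f$intensity)^2)
    } else NA_real_
    data.frame(key = k, residue_index = f$residue_index, ratio = r,
               error = err, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rows$domain <- domain_of(rows$residue_index, dm, stat = TRUE)
  stats_df <- do.call(rbind, lapply(c("REC", "DBD"), function(dn) {
    x <- rows$ratio[!is.na(rows$domain) & rows$domain == dn]
    data.frame(domain = dn, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0, n = length(x))
  }))
  list(ratios = rows, stats = stats_df)
}
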