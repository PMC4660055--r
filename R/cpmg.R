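# CPMG relaxation-dispersion analysis: R2,eff computation with
# duplicate-based errors, per-group model fitting (no-exchange,
# closed-form CR72-MQ, numerical Bloch-McConnell) with multi-start
# optimisation, AIC model selection, the Rex reporting filter, and
# global fitting of grouped methyls sharing one exchange process.

#' Default CPMG refocusing-frequency grid (Hz)
#' @return the measurement grid 50-1000 Hz.
#' @export
nu_cpmg_grid <- function() c(50, 100, 150, 200, 250, 300, 400, 500, 700, 1000)

#' Frequencies measured in duplicate for error estimation (Hz)
#' @return numeric vector.
#' @export
nu_cpmg_duplicates <- function() c(50, 100, 700)

#' Construct a dispersion profile
#'
#' @param group methyl group label (e.g. `"V136"`).
#' @param field_mhz 1H spectrometer frequency (MHz).
#' @param reference_intensity intensity (or vector of intensities) of
#'   the reference spectrum recorded without the CPMG interval.
#' @param points data frame with `nu_cpmg` (Hz, > 0), `intensity`,
#'   `replicate`.
#' @param t_relax constant-time relaxation period (s), default 0.020.
#' @return object of class `dispersion_profile`.
#' @export
dispersion_profile <- function(group, field_mhz, reference_intensity, points,
                               t_relax = 0.020) {
  stopifnot(t_relax > 0, all(points$nu_cpmg > 0))
  if (length(reference_intensity) == 0L || all(!is.finite(reference_intensity)) ||
      mean(reference_intensity) <= 0) {
    stop("reference intensity must be present and positive", call. = FALSE)
  }
  structure(list(group = group, field_mhz = field_mhz, t_relax = t_relax,
                 reference_intensity = mean(reference_intensity),
                 reference_raw = reference_intensity,
                 points = points[order(points$nu_cpmg, points$replicate), ]),
            class = "dispersion_profile")
}

#' Split a dispersion table into per-group, per-field profiles
#'
#' Rows with blank `nu_cpmg` are reference spectra and are attached to
#' the profile of their group/field.
#'
#' @param df data frame from `read_table(..., "dispersion")`.
#' @param t_relax constant-time relaxation period (s).
#' @return nested named list: `profiles[[group]][[field]]`.
#' @export
profiles_from_table <- function(df, t_relax = 0.020) {
  out <- list()
  for (g in unique(df$group)) {
    dg <- df[df$group == g, , drop = FALSE]
    out[[g]] <- list()
    for (f in unique(dg$field_mhz)) {
      dgf <- dg[dg$field_mhz == f, , drop = FALSE]
      ref <- dgf$intensity[is.na(dgf$nu_cpmg)]
      pts <- dgf[!is.na(dgf$nu_cpmg), c("nu_cpmg", "intensity", "replicate")]
      out[[g]][[as.character(f)]] <-
        dispersion_profile(g, f, ref, pts, t_relax = t_relax)
    }
  }
  out
}

#' Compute R2,eff from CPMG intensities
#'
#' \eqn{R_{2,eff}(\nu) = -(1/T)\ln[I(\nu)/I(0)]}. Non-positive
#' intensities cannot be log-transformed and are rejected with a
#' warning. Duplicate measurements are averaged into one point per
#' frequency; the per-replicate values are retained in the
#' `replicates` attribute.
#'
#' @param profile a `dispersion_profile`.
#' @return data frame (`nu_cpmg`, `r2eff`, `n_rep`) of class
#'   `r2eff_curve`, with attributes `replicates`, `field_mhz`,
#'   `t_relax`.
#' @export
r2eff_from_intensities <- function(profile) {
  stopifnot(inherits(profile, "dispersion_profile"))
  pts <- profile$points
  bad <- pts$intensity <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive intensity point(s) rejected")
    pts <- pts[!bad, , drop = FALSE]
  }
  if (nrow(pts) == 0L) stop("all dispersion points rejected", call. = FALSE)
  pts$r2eff <- -log(pts$intensity / profile$reference_intensity) / profile$t_relax
  agg <- stats::aggregate(r2eff ~ nu_cpmg, data = pts, FUN = mean)
  cnt <- stats::aggregate(r2eff ~ nu_cpmg, data = pts, FUN = length)
  curve <- data.frame(nu_cpmg = agg$nu_cpmg, r2eff = agg$r2eff, n_rep = cnt$r2eff)
  attr(curve, "replicates") <- pts[, c("nu_cpmg", "replicate", "r2eff")]
  attr(curve, "field_mhz") <- profile$field_mhz
  attr(curve, "t_relax") <- profile$t_relax
  class(curve) <- c("r2eff_curve", class(curve))
  curve
}

#' Attach duplicate-based errors to an R2,eff curve
#'
#' The pooled standard deviation of R2,eff over all duplicated
#' frequencies is applied uniformly to every point, floored at
#' `floor` s^-1. Without duplicates the configured `noise_floor` is
#' used instead, with a warning.
#'
#' @param profile the source `dispersion_profile`.
#' @param curve output of [r2eff_from_intensities()].
#' @param floor minimum error (s^-1).
#' @param noise_floor fallback error when no frequency was duplicated.
#' @return `curve` with an `error` column.
#' @export
errors_from_duplicates <- function(profile, curve, floor = 0.1, noise_floor = 0.5) {
  reps <- attr(curve, "replicates")
  tab <- table(reps$nu_cpmg)
  dup_nu <- as.numeric(names(tab)[tab >= 2])
  if (length(dup_nu) == 0L) {
    warning("no duplicated frequencies; using configured noise floor")
    curve$error <- rep(noise_floor, nrow(curve))
    return(curve)
  }
  ss <- 0
  dof <- 0
  for (nu in dup_nu) {
    x <- reps$r2eff[reps$nu_cpmg == nu]
    ss <- ss + sum((x - mean(x))^2)
    dof <- dof + length(x) - 1L
  }
  pooled <- sqrt(ss / dof)
  curve$error <- rep(max(pooled, floor), nrow(curve))
  curve
}

.dispersion_model <- function(model) {
  switch(model,
    cr72_mq = function(params, nu, field, t_relax) cr72_mq(params, nu, field),
    ns_mq_2site = ns_mq_2site,
    stop("unknown model: ", model, call. = FALSE)
  )
}

# Finite-difference Jacobian of a residual function; covariance of the
# weighted least-squares estimate is (J'J)^-1 because residuals are
# already scaled by measurement errors.
.lm_cov <- function(res_fn, par) {
  r0 <- res_fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]) * 1e-6, 1e-9)
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (res_fn(pj) - r0) / h
  }
  jtj <- crossprod(J)
  tryCatch(solve(jtj), error = function(e) {
    warning("singular Jacobian: parameter errors unavailable")
    matrix(NA_real_, length(par), length(par))
  })
}

.model_fit <- function(model, params, chi2, n_params, converged = TRUE,
                       errors = NULL) {
  structure(list(model = model, params = params, chi2 = chi2,
                 n_params = n_params, aic = chi2 + 2 * n_params,
                 converged = converged, errors = errors),
            class = "model_fit")
}

#' Fit one methyl group's dispersion curves to an exchange model
#'
#' Weighted least squares over all supplied fields simultaneously.
#' `no_exchange` fits one flat `r2_0` per field (closed form). The
#' exchange models share pB, kex, dw_h, dw_x across fields with a
#' per-field r2_0, optimised from a multi-start grid over
#' kex in [100, 3000] s^-1 and pB in [0.01, 0.45]; the best
#' chi-squared start is kept. The 13C shift difference is constrained
#' non-negative (only the relative 1H/13C sign is observable).
#'
#' @param curves list of `r2eff_curve` objects (with errors), one per
#'   field.
#' @param model `"no_exchange"`, `"cr72_mq"` or `"ns_mq_2site"`.
#' @param kex_starts,pb_starts multi-start grid values.
#' @return a `model_fit`: model name, fitted parameters, chi2, number
#'   of free parameters, `aic = chi2 + 2k`, and covariance-based
#'   standard errors for the exchange models.
#' @export
fit_group <- function(curves, model = c("no_exchange", "cr72_mq", "ns_mq_2site"),
                      kex_starts = c(100, 400, 1200, 3000),
                      pb_starts = c(0.02, 0.10, 0.25, 0.45)) {
  model <- match.arg(model)
  curves <- curves[order(vapply(curves, function(cv) attr(cv, "field_mhz"), numeric(1)))]
  fields <- vapply(curves, function(cv) attr(cv, "field_mhz"), numeric(1))
  if (is.null(curves[[1]]$error)) stop("curves need errors; run errors_from_duplicates",
                                       call. = FALSE)
  y <- unlist(lapply(curves, `[[`, "r2eff"))
  w <- 1 / unlist(lapply(curves, `[[`, "error"))
  nf <- length(fields)

  if (model == "no_exchange") {
    r20 <- vapply(curves, function(cv) {
      stats::weighted.mean(cv$r2eff, 1 / cv$error^2)
    }, numeric(1))
    names(r20) <- as.character(fields)
    pred <- unlist(lapply(seq_len(nf), function(i) {
      rep(r20[i], nrow(curves[[i]]))
    }))
    chi2 <- sum(((y - pred) * w)^2)
    return(.model_fit("no_exchange", list(r2_0 = r20), chi2, nf))
  }

  fun <- .dispersion_model(model)
  predict_par <- function(p) {
    unlist(lapply(seq_len(nf), function(i) {
      pars <- exchange_parameters(pb = p[1], kex = p[2], dw_h = p[3],
                                  dw_x = p[4], r2_0 = p[4 + i])
      fun(pars, curves[[i]]$nu_cpmg, fields[i], attr(curves[[i]], "t_relax"))
    }))
  }
  res_fn <- function(p) (y - predict_par(p)) * w
  r20_start <- vapply(curves, function(cv) min(cv$r2eff), numeric(1))
  lower <- c(1e-4, 1, -5, 0, rep(0, nf))
  upper <- c(0.499, 2e4, 5, 10, rep(500, nf))
  best <- NULL
  for (kx in kex_starts) for (pbs in pb_starts) {
    start <- c(pbs, kx, 0.1, 1.0, r20_start)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2) best <- list(fit = fit, chi2 = chi2)
  }
  if (is.null(best)) {
    stop("no start converged (grid kex=", paste(kex_starts, collapse = "/"),
         ", pB=", paste(pb_starts, collapse = "/"), ")", call. = FALSE)
  }
  p <- unname(best$fit$par)
  r20 <- p[4 + seq_len(nf)]
  names(r20) <- as.character(fields)
  params <- exchange_parameters(pb = p[1], kex = p[2], dw_h = p[3],
                                dw_x = p[4], r2_0 = r20)
  cov <- .lm_cov(res_fn, p)
  # duplicate-based errors carry few degrees of freedom, so treat the
  # weights as relative and rescale the covariance by the reduced chi2
  dof <- length(y) - (4 + nf)
  s2 <- if (dof > 0) best$chi2 / dof else 1
  se <- sqrt(pmax(diag(cov), 0) * s2)
  errors <- c(pb = se[1], kex = se[2], dw_h = se[3], dw_x = se[4])
  .model_fit(model, params, best$chi2, 4 + nf, errors = errors)
}

#' Select a model by AIC
#'
#' AIC = chi2 + 2k over the weighted residual sum; the minimum wins,
#' ties break toward the model with fewer free parameters.
#'
#' @param fits list of `model_fit` objects for the same data.
#' @return the selected `model_fit`.
#' @export
aic_select <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  fits[[order(aic, k)[1]]]
}

#' Rex filter for reporting exchange parameters
#'
#' Rex = R2,eff(50 Hz) - R2,eff(1000 Hz); parameters are reported only
#' for groups whose Rex strictly exceeds 3 s^-1 (at at least one field
#' when several are measured; see [rex_filter_group()]).
#'
#' @param curve an `r2eff_curve` containing the 50 and 1000 Hz points.
#' @param threshold reporting threshold (s^-1).
#' @return list with `rex` and logical `pass`.
#' @export
rex_filter <- function(curve, threshold = 3) {
  i50 <- which(abs(curve$nu_cpmg - 50) < 1e-6)
  i1000 <- which(abs(curve$nu_cpmg - 1000) < 1e-6)
  if (length(i50) != 1L || length(i1000) != 1L) {
    stop("curve must contain nu_CPMG = 50 and 1000 Hz", call. = FALSE)
  }
  rex <- curve$r2eff[i50] - curve$r2eff[i1000]
  list(rex = rex, pass = rex > threshold)
}

#' Rex filter over several fields
#' @param curves list of `r2eff_curve` objects.
#' @param threshold reporting threshold (s^-1).
#' @return list with per-field `rex` values and overall `pass` (any
#'   field strictly above threshold).
#' @export
rex_filter_group <- function(curves, threshold = 3) {
  res <- lapply(curves, rex_filter, threshold = threshold)
  list(rex = vapply(res, `[[`, numeric(1), "rex"),
       pass = any(vapply(res, `[[`, logical(1), "pass")))
}

#' Global two-site exchange fit of several methyl groups
#'
#' All groups share one minor-state population pB and one exchange
#' rate kex; each group keeps its own dw_h, dw_x and per-field r2_0.
#' Groups failing the Rex filter are dropped unless `require_rex =
#' FALSE`. Multi-start optimisation as in [fit_group()]; parameter
#' errors from the covariance of the weighted fit, optionally by
#' Monte-Carlo resampling of the R2,eff data within their errors.
#'
#' @param group_curves named list; element g = list of `r2eff_curve`
#'   objects (with errors) for group g, one per field.
#' @param model dispersion model (default the numerical reference).
#' @param require_rex drop groups failing the Rex filter.
#' @param kex_starts,pb_starts multi-start grid.
#' @param n_mc number of Monte-Carlo resamples (0 = covariance only).
#' @param seed RNG seed for the resampling.
#' @return list of class `global_fit`: `pb`, `kex` (with `pb_se`,
#'   `kex_se`), per-group parameter table, total `chi2`, `n_params`,
#'   `aic`, group names, and optional `mc` block.
#' @export
global_fit <- function(group_curves, model = "ns_mq_2site", require_rex = TRUE,
                       kex_starts = c(100, 400, 1200, 3000),
                       pb_starts = c(0.05, 0.15, 0.35),
                       n_mc = 0, seed = 1L) {
  if (require_rex) {
    keep <- vapply(group_curves, function(cv) rex_filter_group(cv)$pass, logical(1))
    group_curves <- group_curves[keep]
  }
  G <- length(group_curves)
  if (G < 2L) stop("global fit needs >= 2 groups (after Rex filtering)", call. = FALSE)
  gnames <- names(group_curves)
  fields_g <- lapply(group_curves, function(cv) {
    vapply(cv, function(x) attr(x, "field_mhz"), numeric(1))
  })
  fun <- .dispersion_model(model)
  y <- unlist(lapply(group_curves, function(cv) lapply(cv, `[[`, "r2eff")))
  w <- 1 / unlist(lapply(group_curves, function(cv) lapply(cv, `[[`, "error")))

  # parameter layout: pb, kex, then per group (dw_h, dw_x), then per
  # group per field r2_0
  nf_g <- vapply(fields_g, length, integer(1))
  r20_idx <- 2 + 2 * G + c(0, cumsum(nf_g)[-G])
  predict_par <- function(p) {
    unlist(lapply(seq_len(G), function(g) {
      cv <- group_curves[[g]]
      lapply(seq_along(cv), function(i) {
        pars <- exchange_parameters(
          pb = p[1], kex = p[2],
          dw_h = p[2 + 2 * g - 1], dw_x = p[2 + 2 * g],
          r2_0 = p[r20_idx[g] + i])
        fun(pars, cv[[i]]$nu_cpmg, fields_g[[g]][i], attr(cv[[i]], "t_relax"))
      })
    }))
  }
  res_fn <- function(p) (y - predict_par(p)) * w
  r20_start <- unlist(lapply(group_curves, function(cv) {
    vapply(cv, function(x) min(x$r2eff), numeric(1))
  }))
  lower <- c(1e-4, 1, rep(c(-5, 0), G), rep(0, sum(nf_g)))
  upper <- c(0.499, 2e4, rep(c(5, 10), G), rep(500, sum(nf_g)))
  best <- NULL
  for (kx in kex_starts) for (pbs in pb_starts) {
    start <- c(pbs, kx, rep(c(0.1, 1.0), G), r20_start)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2) best <- list(fit = fit, chi2 = chi2)
  }
  if (is.null(best)) stop("global fit: no start converged", call. = FALSE)
  p <- unname(best$fit$par)
  n_params <- length(p)
  at_bound <- p[1] <= lower[1] + 1e-6 || p[1] >= upper[1] - 1e-6
  if (at_bound) warning("minor population at parameter bound: degenerate fit")
  cov <- .lm_cov(res_fn, p)
  dof <- length(y) - n_params
  s2 <- if (dof > 0) best$chi2 / dof else 1  # weights treated as relative
  se <- sqrt(pmax(diag(cov), 0) * s2)
  groups <- data.frame(
    group = gnames,
    dw_h = p[2 + 2 * seq_len(G) - 1],
    dw_x = p[2 + 2 * seq_len(G)],
    stringsAsFactors = FALSE
  )
  r20_tab <- lapply(seq_len(G), function(g) {
    r <- p[r20_idx[g] + seq_len(nf_g[g])]
    names(r) <- as.character(fields_g[[g]])
    r
  })
  names(r20_tab) <- gnames
  out <- structure(list(
    pb = p[1], kex = p[2], pb_se = se[1], kex_se = se[2],
    minor_population_percent = 100 * p[1],
    groups = groups, r2_0 = r20_tab, chi2 = best$chi2,
    n_params = n_params, aic = best$chi2 + 2 * n_params,
    model = model, degenerate = at_bound
  ), class = "global_fit")

  if (n_mc > 0) {
    set.seed(seed)
    sims <- matrix(NA_real_, n_mc, 2)
    yhat <- predict_par(p)
    errs <- 1 / w
    for (m in seq_len(n_mc)) {
      ym <- yhat + stats::rnorm(length(y), 0, errs)
      rf <- function(q) (ym - predict_par(q)) * w
      fm <- tryCatch(
        minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = rf,
                           control = minpack.lm::nls.lm.control(maxiter = 150)),
        error = function(e) NULL)
      if (!is.null(fm)) sims[m, ] <- fm$par[1:2]
    }
    out$mc <- list(pb_se = stats::sd(sims[, 1], na.rm = TRUE),
                   kex_se = stats::sd(sims[, 2], na.rm = TRUE),
                   n_ok = sum(stats::complete.cases(sims)))
  }
  out
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf(
    "global two-site exchange fit (%s, %d groups)\n  minor population: %.1f%% +/- %.1f\n  kex: %.0f +/- %.0f s^-1\n  chi2 = %.3g (k = %d, AIC = %.3g)\n",
    x$model, nrow(x$groups), 100 * x$pb, 100 * x$pb_se, x$kex, x$kex_se,
    x$chi2, x$n_params, x$aic))
  invisible(x)
}
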