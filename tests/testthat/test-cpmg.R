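test_that("R2,eff follows the log-ratio formula and handles bad points", {
  pts <- data.frame(nu_cpmg = c(50, 100), intensity = c(1000, 500), replicate = 1L)
  pr <- dispersion_profile("V26", 600, 1000, pts, t_relax = 0.020)
  cv <- r2eff_from_intensities(pr)
  expect_equal(cv$r2eff[cv$nu_cpmg == 50], 0)
  expect_equal(cv$r2eff[cv$nu_cpmg == 100], log(2) / 0.020, tolerance = 1e-12)

  bad <- dispersion_profile("V26", 600, 1000,
                            data.frame(nu_cpmg = c(50, 100),
                                       intensity = c(-5, 500), replicate = 1L))
  expect_warning(cvb <- r2eff_from_intensities(bad), "rejected")
  expect_equal(nrow(cvb), 1L)
  allbad <- dispersion_profile("V26", 600, 1000,
                               data.frame(nu_cpmg = 50, intensity = 0, replicate = 1L))
  expect_error(suppressWarnings(r2eff_from_intensities(allbad)), "all")
})

test_that("duplicate-based errors pool correctly and respect the floor", {
  # three duplicated frequencies whose pairs differ by 2d in R2,eff
  d <- 0.4
  T <- 0.020
  mk_int <- function(r2) 1000 * exp(-T * r2)
  pts <- data.frame(
    nu_cpmg = rep(c(50, 100, 700), each = 2),
    intensity = mk_int(rep(c(20, 19, 18), each = 2) + c(-d, d)),
    replicate = rep(1:2, 3))
  pr <- dispersion_profile("g", 600, 1000, pts)
  cv <- errors_from_duplicates(pr, r2eff_from_intensities(pr))
  expect_equal(unique(cv$error), d * sqrt(2), tolerance = 1e-9)

  # identical duplicates: pooled SD 0, floored at 0.1
  pts2 <- data.frame(nu_cpmg = rep(c(50, 100, 700), each = 2),
                     intensity = rep(mk_int(c(20, 19, 18)), each = 2),
                     replicate = rep(1:2, 3))
  pr2 <- dispersion_profile("g", 600, 1000, pts2)
  cv2 <- errors_from_duplicates(pr2, r2eff_from_intensities(pr2))
  expect_equal(unique(cv2$error), 0.1)

  # no duplicates: configured fallback with warning
  pr3 <- dispersion_profile("g", 600, 1000,
                            data.frame(nu_cpmg = c(50, 100), intensity = mk_int(c(20, 19)),
                                       replicate = 1L))
  expect_warning(cv3 <- errors_from_duplicates(pr3, r2eff_from_intensities(pr3),
                                               noise_floor = 0.7), "noise floor")
  expect_equal(unique(cv3$error), 0.7)

  # doubling T_relax halves the R2,eff spread from the same intensity noise
  eps <- 0.01
  spread <- function(T) {
    pts <- data.frame(nu_cpmg = rep(50, 2),
                      intensity = 1000 * exp(-T * 20) * c(1 + eps, 1 - eps),
                      replicate = 1:2)
    pr <- dispersion_profile("g", 600, 1000, pts, t_relax = T)
    reps <- attr(r2eff_from_intensities(pr), "replicates")
    diff(range(reps$r2eff))
  }
  expect_equal(spread(0.040) / spread(0.020), 0.5, tolerance = 1e-4)
})

test_that("dispersion models are flat without a minor state or shift difference", {
  nus <- nu_cpmg_grid()
  p0 <- exchange_parameters(1e-6, 560, 0.1, 1.0, r2_0 = 20)
  expect_lt(max(abs(ns_mq_2site(p0, nus, 850) - 20)), 1e-3)
  expect_lt(max(abs(cr72_mq(p0, nus, 850) - 20)), 1e-3)
  pflat <- exchange_parameters(0.11, 560, 0, 0, r2_0 = 20)
  expect_equal(cr72_mq(pflat, nus, 850), rep(20, length(nus)))
  expect_lt(max(abs(ns_mq_2site(pflat, nus, 850) - 20)), 1e-9)
  expect_error(exchange_parameters(0.11, -5, 0.1, 1, 20), "kex")
  expect_error(exchange_parameters(1.4, 500, 0.1, 1, 20), "pb")
})

test_that("closed form and numerical propagation agree in the fast regime", {
  nus <- nu_cpmg_grid()
  set.seed(101)
  for (i in 1:25) {
    pb <- runif(1, 0.01, 0.2)
    kex <- runif(1, 1000, 8000)
    dh <- runif(1, -0.5, 0.5)
    dx <- runif(1, 0, 3)
    for (f in c(600, 850)) {
      pe <- exchange_parameters(pb, kex, dh, dx, r2_0 = 20)
      expect_lt(max(abs(cr72_mq(pe, nus, f) - ns_mq_2site(pe, nus, f))), 0.5)
    }
  }
})

test_that("model curves never dip below r2_0 and obey exchange symmetry", {
  nus <- nu_cpmg_grid()
  set.seed(102)
  for (i in 1:20) {
    pb <- runif(1, 0.01, 0.3)
    kex <- runif(1, 200, 6000)
    dh <- runif(1, -0.3, 0.3)
    dx <- runif(1, 0, 2.5)
    pe <- exchange_parameters(pb, kex, dh, dx, r2_0 = 20)
    for (f in c(600, 850)) {
      expect_gt(min(ns_mq_2site(pe, nus, f)) - 20, -1e-6)
      expect_gt(min(cr72_mq(pe, nus, f)) - 20, -1e-6)
    }
    # negating both shift differences leaves curves unchanged (only the
    # relative 1H/13C sign is observable)
    pneg <- exchange_parameters(pb, kex, -dh, dx, r2_0 = 20)
    pneg$dw_x <- -dx
    expect_equal(ns_mq_2site(pneg, nus, 850), ns_mq_2site(pe, nus, 850),
                 tolerance = 1e-9)
    expect_equal(cr72_mq(pneg, nus, 850), cr72_mq(pe, nus, 850),
                 tolerance = 1e-9)
  }
})

test_that("profiles are monotone non-increasing when exchange outruns the shift", {
  nus <- nu_cpmg_grid()
  set.seed(103)
  for (i in 1:30) {
    pb <- runif(1, 0.01, 0.3)
    dx <- runif(1, 0.05, 3)
    for (f in c(600, 850)) {
      dwc <- abs(ppm_to_rad(dx, f, "C"))
      kex <- runif(1, 0.5 * dwc, 0.5 * dwc + 5000)
      pe <- exchange_parameters(pb, kex, 0, dx, r2_0 = 20)
      expect_lt(max(diff(ns_mq_2site(pe, nus, f))), 1e-4)
    }
  }
})

test_that("group fits recover noiseless closed-form parameters to 4 digits", {
  truth <- exchange_parameters(0.12, 900, 0.08, 1.1,
                               r2_0 = c(`600` = 15, `850` = 19))
  curves <- curves_from_model(truth, model = function(p, nu, f, t) cr72_mq(p, nu, f, t))
  fit <- fit_group(curves, "cr72_mq")
  expect_equal(fit$params$pb, 0.12, tolerance = 1e-4)
  expect_equal(fit$params$kex, 900, tolerance = 1e-4 * 900)
  expect_equal(abs(fit$params$dw_x), 1.1, tolerance = 1e-3)
  expect_equal(fit$model, "cr72_mq")
  expect_equal(fit$n_params, 6)

  # swapping the field order leaves the fit unchanged
  fit2 <- fit_group(rev(curves), "cr72_mq")
  expect_equal(fit2$params$kex, fit$params$kex, tolerance = 1e-6)
})

test_that("AIC selection uses chi2 + 2k with ties toward simplicity", {
  a <- fake_fit(50, 2, "simple")
  b <- fake_fit(30, 6, "rich")
  expect_equal(a$aic, 54)
  expect_equal(b$aic, 42)
  expect_equal(aic_select(list(a, b))$model, "rich")
  # equal AIC: fewer parameters win
  tie <- fake_fit(46, 4, "mid")   # aic 54 as well
  expect_equal(aic_select(list(tie, a))$model, "simple")
  # a parameter that buys exactly 2 chi2 leaves AIC unchanged
  expect_equal(fake_fit(48, 3)$aic, fake_fit(50, 2)$aic)
  expect_error(aic_select(list()), "empty")
})

test_that("exchange models are not selected for exchange-free data", {
  wins <- vapply(1:10, function(s) {
    set.seed(500 + s)
    curves <- curves_from_model(exchange_parameters(1e-4, 1000, 0, 0, r2_0 = 20),
                                error = 0.3)
    for (i in seq_along(curves)) {
      curves[[i]]$r2eff <- curves[[i]]$r2eff + rnorm(nrow(curves[[i]]), 0, 0.3)
    }
    ne <- fit_group(curves, "no_exchange")
    # the exchange fit of flat data is legitimately degenerate, so the
    # singular-covariance warning is expected
    ex <- suppressWarnings(fit_group(curves, "cr72_mq",
                                     kex_starts = c(200, 2000),
                                     pb_starts = c(0.05, 0.3)))
    (ne$aic - ex$aic) < 2
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("Rex filter applies the strict 3/s threshold at 50 vs 1000 Hz", {
  mk <- function(r50, r1000) {
    cv <- data.frame(nu_cpmg = c(50, 200, 1000), r2eff = c(r50, 22, r1000),
                     n_rep = 1L)
    attr(cv, "field_mhz") <- 600
    class(cv) <- c("r2eff_curve", class(cv))
    cv
  }
  flat <- rex_filter(mk(20, 20))
  expect_equal(flat$rex, 0)
  expect_false(flat$pass)
  ok <- rex_filter(mk(25, 21.5))
  expect_equal(ok$rex, 3.5)
  expect_true(ok$pass)
  # exactly at the threshold fails (strict inequality)
  expect_false(rex_filter(mk(24, 21))$pass)
  expect_error(rex_filter(mk(25, 21.5)[1:2, ]), "1000")
  # multi-field: pass if either field passes
  expect_true(rex_filter_group(list(mk(20, 20), mk(25, 21)))$pass)
  expect_false(rex_filter_group(list(mk(20, 20), mk(22, 20)))$pass)
})

test_that("global fits share one exchange process and detect misfit", {
  truth <- dispersion_truth_defaults()[1:3]
  gc <- noisy_group_curves(truth, seed = 7)
  fit <- global_fit(gc)
  expect_equal(fit$kex, 560, tolerance = 0.10 * 560)
  expect_lt(abs(fit$pb - 0.11), 0.03)
  expect_equal(nrow(fit$groups), 3L)

  # individual fits scatter more than the shared estimate
  ind <- vapply(names(gc), function(g) fit_group(gc[[g]], "ns_mq_2site")$params$kex,
                numeric(1))
  expect_gt(sd(ind), 1e-6)

  # a group with a different exchange rate inflates the global chi2
  mixed <- truth
  mixed$L134 <- exchange_parameters(0.11, 2500, mixed$L134$dw_h, mixed$L134$dw_x,
                                    r2_0 = mixed$L134$r2_0)
  gc2 <- noisy_group_curves(mixed, seed = 7)
  fit2 <- global_fit(gc2)
  ind2 <- sum(vapply(names(gc2), function(g) {
    fit_group(gc2[[g]], "ns_mq_2site")$chi2
  }, numeric(1)))
  expect_gt(fit2$chi2, ind2 + 50)

  # duplicating a group leaves shared estimates essentially unchanged
  gc3 <- c(gc, list(V26bis = gc$V26))
  fit3 <- global_fit(gc3)
  expect_equal(fit3$kex, fit$kex, tolerance = 0.05 * fit$kex)
  expect_error(global_fit(gc[1]), ">= 2 groups")
})

test_that("Monte-Carlo resampling yields finite parameter errors", {
  gc <- noisy_group_curves(dispersion_truth_defaults()[1:2], seed = 11)
  fit <- global_fit(gc, n_mc = 10, seed = 4)
  expect_true(is.finite(fit$mc$kex_se))
  expect_gt(fit$mc$kex_se, 0)
  expect_gt(fit$mc$n_ok, 5)
})
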