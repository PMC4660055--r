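test_that("noiseless rate fits recover the generating parameters", {
  t2 <- r2_delays()
  f2 <- fit_r2_decay(t2, 100 * exp(-20 * t2))
  expect_equal(f2$rate, 20, tolerance = 1e-6)
  expect_equal(f2$amplitude, 100, tolerance = 1e-6)

  t1 <- r1_delays()
  f1 <- fit_r1_recovery(t1, 1 - 2 * exp(-1 * t1))
  expect_equal(f1$rate, 1, tolerance = 1e-6)
  expect_equal(f1$amplitude, 1, tolerance = 1e-5)
  expect_equal(f1$offset, -1, tolerance = 1e-5)
})

test_that("rate fits are scale-equivariant and order-invariant", {
  t2 <- r2_delays()
  y <- 100 * exp(-20 * t2)
  base <- fit_r2_decay(t2, y)
  scaled <- fit_r2_decay(t2, 5 * y)
  expect_equal(scaled$rate, base$rate, tolerance = 1e-8)
  expect_equal(scaled$amplitude, 5 * base$amplitude, tolerance = 1e-8)
  ord <- sample(seq_along(t2))
  perm <- fit_r2_decay(t2[ord], y[ord])
  expect_equal(perm$rate, base$rate, tolerance = 1e-8)
})

test_that("rate fit error paths trigger", {
  expect_error(fit_r2_decay(c(0.1, 0.2), c(10, 5)), "3 distinct")
  expect_error(fit_r2_decay(r2_delays(), rep(5, 8)), "unidentifiable")
  expect_error(fit_r1_recovery(c(0.1, 0.2, 0.3), c(1, 2, 3)), "4 distinct")
  expect_warning(fit_r1_recovery(r1_delays(), 2 * exp(-r1_delays()) - 1 +
                                   0.001 * seq_along(r1_delays())),
                 "not recovering")
})

test_that("noisy rate recovery stays within a few percent (simulation)", {
  rel_err <- function(experiment, rate, n_seed = 100) {
    errs <- vapply(seq_len(n_seed), function(s) {
      df <- gen_relaxation_series(data.frame(residue_index = 1, rate = rate),
                                  experiment, noise = 0.01, seed = 1000 + s)
      fit <- if (experiment == "R2") {
        fit_r2_decay(df$delay_s, df$intensity)
      } else {
        # recovery runs -i0 .. i0; generator uses that convention
        fit_r1_recovery(df$delay_s, df$intensity)
      }
      abs(fit$rate - rate) / rate
    }, numeric(1))
    median(errs)
  }
  expect_lt(rel_err("R2", 20), 0.02)
  expect_lt(rel_err("R1", 1.5), 0.03)
})

test_that("rotational correlation time reproduces the per-domain estimates", {
  # DBD mean ratio at 850 MHz: ~14 ns
  expect_equal(tau_c_from_r2r1(40.1, 850), 14.12, tolerance = 1e-3)
  # REC mean ratio: the single-field estimator gives 19.1 ns
  expect_equal(tau_c_from_r2r1(72.5, 850), 19.11, tolerance = 1e-3)
  expect_equal(tau_c_from_r2r1(7 / 6, 850), 0)
  expect_error(tau_c_from_r2r1(1.0, 850), "imaginary")
  # strictly increasing in the ratio, decreasing in the field
  expect_true(tau_c_from_r2r1(50, 850) > tau_c_from_r2r1(40, 850))
  expect_true(tau_c_from_r2r1(40, 600) > tau_c_from_r2r1(40, 850))
})

test_that("domain R2/R1 statistics aggregate correctly", {
  rates <- data.frame(residue_index = c(10, 20, 130, 140),
                      r1 = c(1, 1, 1, 1), r2 = c(40, 44, 40, 44))
  st <- domain_r2r1(rates)
  expect_equal(st$mean[st$domain == "REC"], 42)
  expect_equal(st$sd[st$domain == "REC"], sd(c(40, 44)))
  # permutation invariance
  st2 <- domain_r2r1(rates[c(3, 1, 4, 2), ])
  expect_equal(st2$mean, st$mean)

  # single-residue domain flagged, SD reported as 0
  one <- domain_r2r1(data.frame(residue_index = c(10, 130),
                                r1 = c(48.9 / 72.5, 1), r2 = c(48.9, 40)))
  expect_equal(one$mean[one$domain == "REC"], 72.5, tolerance = 1e-9)
  expect_true(one$n1[one$domain == "REC"])
  expect_equal(one$sd[one$domain == "REC"], 0)

  # residues missing a rate are excluded and listed
  miss <- domain_r2r1(data.frame(residue_index = c(10, 20, 130),
                                 r1 = c(1, NA, 1), r2 = c(40, 44, 42)))
  expect_equal(attr(miss, "excluded"), 20)
  expect_error(domain_r2r1(data.frame(residue_index = 10, r1 = 1, r2 = 40)),
               "DBD")
})

test_that("intensity ratios handle identity, uniform attenuation and doubling", {
  base <- base_amide_peaks()
  same <- gen_csp_peaklists(base)
  ir <- intensity_ratios(same$bound, same$free)
  expect_true(all(abs(ir$ratios$ratio - 1) < 1e-9))

  half <- gen_csp_peaklists(base, attenuation = 0.5)
  ir2 <- intensity_ratios(half$bound, half$free)
  expect_true(all(abs(ir2$ratios$ratio - 0.5) < 1e-9))
  expect_equal(ir2$stats$sd, c(0, 0), tolerance = 1e-9)

  # doubled bound peaks contribute their summed intensity
  dbl <- gen_csp_peaklists(base, doubled = "V130N-H")
  ir3 <- intensity_ratios(dbl$bound, dbl$free)
  expect_equal(ir3$ratios$ratio[ir3$ratios$key == "V130N-H"], 1, tolerance = 1e-9)

  # quadrature error propagation with a noise floor
  irn <- intensity_ratios(half$bound, half$free, noise_floor = 1e4)
  r <- irn$ratios[1, ]
  expect_equal(r$error, r$ratio * sqrt((1e4 / 5e5)^2 + (1e4 / 1e6)^2),
               tolerance = 1e-9)
})

test_that("domain intensity-ratio means are recovered from simulated truth", {
  rec_res <- seq(5, 110, by = 3)
  dbd_res <- seq(127, 210, by = 3)
  base <- base_amide_peaks(c(rec_res, dbd_res))
  means <- t(vapply(1:50, function(s) {
    set.seed(3000 + s)
    att <- c(pmax(rnorm(length(rec_res), 0.46, 0.10), 0.01),
             pmax(rnorm(length(dbd_res), 0.19, 0.09), 0.01))
    names(att) <- sub("_(a|b)$", "", base$token)
    pair <- gen_csp_peaklists(base, attenuation = att)
    st <- intensity_ratios(pair$bound, pair$free)$stats
    c(st$mean[st$domain == "REC"], st$mean[st$domain == "DBD"])
  }, numeric(2)))
  se_rec <- 0.10 / sqrt(length(rec_res)) / sqrt(50)
  se_dbd <- 0.09 / sqrt(length(dbd_res)) / sqrt(50)
  expect_lt(abs(mean(means[, 1]) - 0.46), se_rec)
  expect_lt(abs(mean(means[, 2]) - 0.19), se_dbd)
})
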