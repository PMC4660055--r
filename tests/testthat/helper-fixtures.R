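# Shared fixture builders. Everything is generated in code; no data
# files are read.

# a small amide peak list spanning REC and DBD residues
base_amide_peaks <- function(residues = c(5, 10, 30, 130, 150, 200)) {
  data.frame(
    token = paste0("V", residues, "N-H"),
    shift_x = 110 + seq_along(residues),
    shift_h = 7.5 + 0.1 * seq_along(residues),
    intensity = 1e6,
    stringsAsFactors = FALSE
  )
}

# dispersion curves computed straight from a model, with constant errors
curves_from_model <- function(params, fields = c(600, 850), model = ns_mq_2site,
                              nus = sort(c(nu_cpmg_grid(), nu_cpmg_duplicates())),
                              t_relax = 0.020, error = 0.1) {
  out <- lapply(fields, function(f) {
    nu_u <- unique(nus)
    cv <- data.frame(nu_cpmg = nu_u,
                     r2eff = model(params, nu_u, f, t_relax),
                     n_rep = as.integer(table(nus)[as.character(nu_u)]))
    cv$error <- error
    attr(cv, "field_mhz") <- f
    attr(cv, "t_relax") <- t_relax
    class(cv) <- c("r2eff_curve", class(cv))
    cv
  })
  names(out) <- as.character(fields)
  out
}

# curves with errors from a generated noisy dataset, for one group
noisy_group_curves <- function(truth, seed, noise = 0.02) {
  df <- gen_dispersion_dataset(truth, seed = seed, noise = noise)
  profs <- profiles_from_table(df)
  lapply(profs, function(pf) {
    lapply(pf, function(p) {
      cv <- r2eff_from_intensities(p)
      errors_from_duplicates(p, cv)
    })
  })
}

# bare model_fit for aic_select arithmetic tests
fake_fit <- function(chi2, k, model = "m") {
  structure(list(model = model, params = NULL, chi2 = chi2, n_params = k,
                 aic = chi2 + 2 * k, converged = TRUE),
            class = "model_fit")
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}
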