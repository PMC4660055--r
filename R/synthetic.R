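# Seeded generators producing inputs with the statistical structure
# each analysis stage assumes: duplicate mono-exponential relaxation
# series, two-field MQ dispersion datasets on the measurement grid,
# paired free/bound peak lists, and FP titrations with ligand
# depletion. Each generator seeds the RNG once from its `seed`
# argument, so identical arguments give bit-identical output.

#' Generate duplicate relaxation series
#'
#' Mono-exponential decays (R2) or three-parameter inversion
#' recoveries (R1) with Gaussian intensity noise, measured in
#' duplicate on the default delay schedules.
#'
#' @param truth data frame with `residue_index` and `rate` (s^-1).
#' @param experiment `"R1"` or `"R2"`.
#' @param delays delay schedule in seconds (defaults to the
#'   experiment's standard schedule).
#' @param i0 reference intensity (for R1 the recovery runs from `-i0`
#'   to `+i0`).
#' @param noise Gaussian noise as a fraction of `i0`.
#' @param n_rep number of replicates.
#' @param seed RNG seed.
#' @return relaxation-schema data frame (see [read_table()]).
#' @export
gen_relaxation_series <- function(truth, experiment = c("R2", "R1"),
                                  delays = NULL, i0 = 100, noise = 0.01,
                                  n_rep = 2, seed = 1L) {
  experiment <- match.arg(experiment)
  if (nrow(truth) == 0L) stop("empty truth set", call. = FALSE)
  if (is.null(delays)) delays <- if (experiment == "R2") r2_delays() else r1_delays()
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (rep in seq_len(n_rep)) {
      ideal <- if (experiment == "R2") {
        i0 * exp(-truth$rate[i] * delays)
      } else {
        i0 - 2 * i0 * exp(-truth$rate[i] * delays)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = truth$residue_index[i], experiment = experiment,
        delay_s = delays, intensity = ideal + stats::rnorm(length(delays), 0, noise * i0),
        replicate = rep)
    }
  }
  do.call(rbind, rows)
}

#' Default exchange-parameter truth set for the five interface methyls
#'
#' Emulates the transiently formed receiver-domain/DNA-binding-domain
#' interface: all groups share one exchange process (minor population
#' 11%, kex = 560 s^-1) and differ in their methyl shift differences
#' (1H a few hundredths of a ppm, 13C a fraction of a ppm to ~1.5 ppm,
#' typical of methyl probes) and exchange-free rates per field. With
#' these values every group shows a clear positive dispersion (Rex
#' well above the 3 s^-1 reporting threshold), matching the behaviour
#' described for the interface methyls.
#'
#' @return named list of `exchange_parameters`.
#' @export
dispersion_truth_defaults <- function() {
  dw <- list(V26 = c(0.05, 1.20), I127 = c(0.03, 0.80), L134 = c(0.04, 1.50),
             V136 = c(0.06, 1.00), L140 = c(0.02, 0.60))
  lapply(dw, function(d) {
    exchange_parameters(pb = 0.11, kex = 560, dw_h = d[1], dw_x = d[2],
                        r2_0 = c(`600` = 16, `850` = 21))
  })
}

#' Generate a two-field MQ dispersion dataset
#'
#' Intensities \eqn{I = I(0) e^{-T R_{2,eff}}} with Gaussian noise,
#' where R2,eff comes from the numerical Bloch-McConnell model.
#' Duplicate measurements at 50/100/700 Hz and a reference row per
#' field are included, matching the experimental design.
#'
#' @param truth named list of `exchange_parameters`, one per methyl
#'   group.
#' @param fields spectrometer fields in MHz.
#' @param grid CPMG frequency grid in Hz.
#' @param duplicates frequencies measured twice.
#' @param t_relax constant-time relaxation period (s).
#' @param i0 reference intensity.
#' @param noise Gaussian intensity noise as a fraction of `i0`.
#' @param seed RNG seed.
#' @return dispersion-schema data frame (blank `nu_cpmg` = reference).
#' @export
gen_dispersion_dataset <- function(truth, fields = c(600, 850),
                                   grid = nu_cpmg_grid(),
                                   duplicates = nu_cpmg_duplicates(),
                                   t_relax = 0.020, i0 = 1e6, noise = 0.02,
                                   seed = 1L) {
  stopifnot(length(truth) >= 1L, !is.null(names(truth)))
  set.seed(seed)
  nus <- sort(c(grid, duplicates))
  reps <- as.integer(stats::ave(nus, nus, FUN = seq_along))
  rows <- list()
  for (g in names(truth)) {
    for (f in fields) {
      r2 <- ns_mq_2site(truth[[g]], nus, f, t_relax)
      ideal <- i0 * exp(-t_relax * r2)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, field_mhz = f, nu_cpmg = c(NA, nus),
        intensity = c(i0, ideal) + stats::rnorm(length(nus) + 1L, 0, noise * i0),
        replicate = c(1L, reps))
    }
  }
  do.call(rbind, rows)
}

#' Generate paired free/bound peak lists
#'
#' The bound list applies prescribed shift perturbations and intensity
#' attenuations to the free list, duplicates assignments in the
#' doubled set (intensity split between variants, the second variant
#' perturbed further by `doubled_extra` ppm in the 1H dimension), and
#' omits the missing set.
#'
#' @param base data frame with `token`, `shift_x`, `shift_h`,
#'   `intensity` describing the free-state peaks.
#' @param perturb_h,perturb_x named numeric vectors (by assignment
#'   key) of bound-state shift changes in ppm; unnamed scalar applies
#'   to all.
#' @param attenuation named numeric vector (or scalar) of
#'   bound/free intensity ratios.
#' @param doubled assignment keys gaining a second bound variant.
#' @param missing assignment keys absent from the bound list.
#' @param doubled_extra extra 1H offset of the `b` variant (ppm).
#' @return list with `free` and `bound` `peak_list` objects.
#' @export
gen_csp_peaklists <- function(base, perturb_h = 0, perturb_x = 0,
                              attenuation = 1, doubled = character(),
                              missing = character(), doubled_extra = 0.05) {
  if (length(intersect(doubled, missing))) {
    stop("doubled and missing sets overlap: ",
         paste(intersect(doubled, missing), collapse = ","), call. = FALSE)
  }
  val_for <- function(v, key) {
    if (is.null(names(v))) v[1] else if (key %in% names(v)) v[[key]] else 0
  }
  att_for <- function(v, key) {
    if (is.null(names(v))) v[1] else if (key %in% names(v)) v[[key]] else 1
  }
  free_lines <- sprintf("%s %.6f %.6f %.6g", base$token, base$shift_x,
                        base$shift_h, base$intensity)
  bound_lines <- character()
  for (i in seq_len(nrow(base))) {
    key <- sub("_(a|b)$", "", base$token[i])
    if (key %in% missing) next
    sx <- base$shift_x[i] + val_for(perturb_x, key)
    sh <- base$shift_h[i] + val_for(perturb_h, key)
    int <- base$intensity[i] * att_for(attenuation, key)
    if (key %in% doubled) {
      bound_lines <- c(bound_lines,
        sprintf("%s %.6f %.6f %.6g", key, sx, sh, int / 2),
        sprintf("%s_b %.6f %.6f %.6g", key, sx, sh + doubled_extra, int / 2))
    } else {
      bound_lines <- c(bound_lines, sprintf("%s %.6f %.6f %.6g", key, sx, sh, int))
    }
  }
  list(free = read_sparky_list(free_lines, "free"),
       bound = read_sparky_list(bound_lines, "bound"))
}

#' Generate a synthetic FP titration
#'
#' Polarization from the exact one-site ligand-depletion model plus
#' Gaussian noise, in replicate.
#'
#' @param kd dissociation constant (nM, > 0).
#' @param p_free,p_bound polarization of free and bound DNA (mP).
#' @param dna_total labelled DNA concentration (nM).
#' @param conc protein concentration grid (nM).
#' @param noise Gaussian polarization noise (mP).
#' @param replicates number of replicate measurements.
#' @param seed RNG seed.
#' @return titration-schema data frame.
#' @export
gen_fp_titration <- function(kd, p_free = 60, p_bound = 180, dna_total = 6,
                             conc = round(exp(seq(log(10), log(3000), length.out = 12))),
                             noise = 2, replicates = 3, seed = 1L) {
  if (kd <= 0) stop("kd must be positive", call. = FALSE)
  set.seed(seed)
  theta <- fraction_bound(conc, kd, dna_total)
  ideal <- p_free + (p_bound - p_free) * theta
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(protein_nM = conc,
               polarization_mP = ideal + stats::rnorm(length(conc), 0, noise),
               replicate = r)
  }))
}
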