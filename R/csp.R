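# Weighted chemical-shift perturbation (CSP) analysis between the free
# and DNA-bound states. Amide CSPs down-weight 15N by 1/5, methyl CSPs
# weight 13C by 0.3, both averaged over the two dimensions inside the
# square root; Leu/Val residues report the mean of their two methyls.

#' Weighted amide chemical-shift perturbation
#'
#' \eqn{\Delta\delta = \sqrt{(\Delta\delta_{HN}^2 + (\Delta\delta_N/5)^2)/2}}
#'
#' @param delta_hn 1H shift difference (ppm).
#' @param delta_n 15N shift difference (ppm).
#' @return combined CSP (ppm, >= 0).
#' @export
weighted_csp_amide <- function(delta_hn, delta_n) {
  if (!all(is.finite(delta_hn)) || !all(is.finite(delta_n))) {
    stop("non-finite shift difference", call. = FALSE)
  }
  sqrt((delta_hn^2 + (delta_n / 5)^2) / 2)
}

#' Weighted methyl chemical-shift perturbation
#'
#' \eqn{\Delta\delta = \sqrt{(\Delta\delta_H^2 + (0.3\,\Delta\delta_C)^2)/2}}
#'
#' @param delta_h 1H shift difference (ppm).
#' @param delta_c 13C shift difference (ppm).
#' @return combined CSP (ppm, >= 0).
#' @export
weighted_csp_methyl <- function(delta_h, delta_c) {
  if (!all(is.finite(delta_h)) || !all(is.finite(delta_c))) {
    stop("non-finite shift difference", call. = FALSE)
  }
  sqrt((delta_h^2 + (0.3 * delta_c)^2) / 2)
}

.csp_one <- function(group, dh, dx) {
  if (group == "amide") weighted_csp_amide(dh, dx) else weighted_csp_methyl(dh, dx)
}

#' Match free and bound peak lists into CSP records
#'
#' Peaks are matched by assignment. Assignments with two bound-state
#' variants get status `doubled` (both per-variant deltas kept, the
#' larger reported as `delta_max`, their mean used as the single
#' `delta` entering threshold statistics). Assignments present only in
#' the free list are `missing_in_bound`; bound-only assignments are
#' `appeared_in_bound`; neither carries a delta.
#'
#' @param free,bound `peak_list` objects for the two states.
#' @return data frame with one row per assignment: `key`,
#'   `residue_index`, `residue_type`, `group`, `status`, `delta`,
#'   `delta_a`, `delta_b`, `delta_max`.
#' @export
pair_states <- function(free, bound) {
  fr <- free[free$variant == "a", , drop = FALSE]
  keys <- union(fr$key, bound$key)
  out <- lapply(keys, function(k) {
    f <- fr[fr$key == k, , drop = FALSE]
    b <- bound[bound$key == k, , drop = FALSE]
    ref <- if (nrow(f)) f[1, ] else b[1, ]
    row <- data.frame(
      key = k, residue_index = ref$residue_index,
      residue_type = ref$residue_type, group = ref$group,
      status = NA_character_, delta = NA_real_, delta_a = NA_real_,
      delta_b = NA_real_, delta_max = NA_real_, stringsAsFactors = FALSE
    )
    if (nrow(f) == 0L) {
      row$status <- "appeared_in_bound"
    } else if (nrow(b) == 0L) {
      row$status <- "missing_in_bound"
    } else {
      d <- vapply(seq_len(nrow(b)), function(i) {
        .csp_one(ref$group, b$shift_h[i] - f$shift_h, b$shift_x[i] - f$shift_x)
      }, numeric(1))
      if (nrow(b) >= 2L) {
        row$status <- "doubled"
        row$delta_a <- d[b$variant == "a"][1]
        row$delta_b <- d[b$variant == "b"][1]
        row$delta <- mean(d)
        row$delta_max <- max(d)
      } else {
        row$status <- "matched"
        row$delta <- d
        row$delta_max <- d
      }
    }
    row
  })
  out <- do.call(rbind, out)
  out[order(out$residue_index, out$key), ]
}

#' Per-residue CSPs with the Leu/Val two-methyl mean rule
#'
#' Methyl CSP records are collapsed to one value per residue: Ile uses
#' its single delta1 methyl, Leu and Val the mean of their two methyl
#' CSPs (when both are present).
#'
#' @param records output of [pair_states()] restricted to methyls.
#' @return data frame `residue_index`, `residue_type`, `delta`, `n_methyl`.
#' @export
residue_methyl_csp <- function(records) {
  recs <- records[records$group != "amide" & !is.na(records$delta), , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(data.frame(residue_index = integer(), residue_type = character(),
                      delta = numeric(), n_methyl = integer()))
  }
  agg <- stats::aggregate(delta ~ residue_index + residue_type, data = recs, FUN = mean)
  cnt <- stats::aggregate(delta ~ residue_index + residue_type, data = recs, FUN = length)
  agg$n_methyl <- cnt$delta
  agg[order(agg$residue_index), ]
}

#' Flag significant CSPs against a mean + 1 SD threshold
#'
#' The threshold is mean(delta) + 1 sample standard deviation over all
#' records that carry a delta; significance requires strict exceedance.
#'
#' @param records data frame with a `delta` column (NA allowed for
#'   missing/appeared records, which never gain a flag).
#' @return `records` with logical `significant` column; the threshold
#'   is attached as attribute `threshold` (also `mean` and `sd`).
#' @export
flag_significant <- function(records) {
  d <- records$delta[!is.na(records$delta)]
  if (length(d) < 2L) stop("need >= 2 CSP values to set a threshold", call. = FALSE)
  thr <- mean(d) + stats::sd(d)
  records$significant <- !is.na(records$delta) & records$delta > thr
  attr(records, "threshold") <- thr
  attr(records, "mean") <- mean(d)
  attr(records, "sd") <- stats::sd(d)
  records
}

#' Full CSP analysis of a free/bound peak-list pair
#'
#' Pairs states, collapses Leu/Val methyls per residue for the
#' threshold statistics, and flags significance separately for amides
#' and methyls (the two probe types have different CSP scales).
#'
#' @param free,bound `peak_list` objects.
#' @return list with `records` (all per-assignment records), `amide`
#'   and `methyl` flagged tables (per residue for methyls) and the two
#'   thresholds.
#' @export
csp_analysis <- function(free, bound) {
  rec <- pair_states(free, bound)
  amide <- rec[rec$group == "amide", , drop = FALSE]
  out <- list(records = rec)
  if (sum(!is.na(amide$delta)) >= 2L) {
    amide <- flag_significant(amide)
    out$amide <- amide
    out$amide_threshold <- attr(amide, "threshold")
  }
  meth <- residue_methyl_csp(rec)
  if (nrow(meth) >= 2L) {
    meth <- flag_significant(meth)
    out$methyl <- meth
    out$methyl_threshold <- attr(meth, "threshold")
  }
  out
}
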