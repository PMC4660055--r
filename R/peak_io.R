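# Readers and writers for the tabular experiment formats the pipeline
# consumes: Sparky-style peak lists and CSV tables for relaxation,
# dispersion, titration and reporter data.

.pmra_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Read a Sparky-style peak list
#'
#' Each data line is `Assignment w1 w2 Height`, where `w1` is the
#' heteronucleus shift (15N for amides, 13C for methyls, ppm), `w2`
#' the 1H shift (ppm) and `Height` the peak intensity. A header line
#' starting with `Assignment` is skipped. Malformed lines do not abort
#' the read: they are collected as per-line error records in the
#' `errors` attribute.
#'
#' @param input path to a file, or a character vector of lines.
#' @param state peak state label, `"free"` or `"bound"`.
#' @return a `peak_list` data frame with columns `key`,
#'   `residue_index`, `residue_type`, `group`, `variant`, `shift_x`,
#'   `shift_h`, `intensity`, `state`; attribute `errors` holds a data
#'   frame of (line, text, reason) for rejected lines.
#' @export
read_sparky_list <- function(input, state = c("free", "bound")) {
  state <- match.arg(state)
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- as.character(lines)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^\\s*Assignment", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty peak list", call. = FALSE)

  rows <- vector("list", length(idx))
  errs <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    rec <- tryCatch({
      if (length(fields) != 4L) stop("expected 4 fields, got ", length(fields))
      a <- parse_assignment(fields[1])
      sx <- suppressWarnings(as.numeric(fields[2]))
      sh <- suppressWarnings(as.numeric(fields[3]))
      ht <- suppressWarnings(as.numeric(fields[4]))
      if (any(is.na(c(sx, sh, ht)))) stop("malformed shift or intensity")
      if (ht < 0) stop("negative intensity")
      data.frame(
        key = a$key, residue_index = a$residue_index,
        residue_type = a$residue_type, group = a$group,
        variant = a$variant, shift_x = sx, shift_h = sh,
        intensity = ht, state = state, stringsAsFactors = FALSE
      )
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = i, text = lines[i], reason = conditionMessage(rec),
        stringsAsFactors = FALSE
      )
      .pmra_log("WARN", "line ", i, " rejected: ", conditionMessage(rec))
      rows[[k]] <- NULL
    } else {
      rows[[k]] <- rec
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no parseable peaks in list", call. = FALSE)
  pl <- do.call(rbind, rows)
  dup <- duplicated(pl[, c("key", "variant")])
  if (any(dup)) {
    stop("duplicate assignment in peak list: ",
         paste(unique(pl$key[dup]), collapse = ", "), call. = FALSE)
  }
  attr(pl, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), text = character(), reason = character())
  class(pl) <- c("peak_list", class(pl))
  pl
}

#' Read a peak list from the CSV alternative format
#'
#' Columns `assignment`, `w1`, `w2`, `height` with the same field
#' semantics as the Sparky dialect (w1 = heteronucleus ppm, w2 = 1H
#' ppm). Rows are validated through the same parser.
#'
#' @inheritParams read_sparky_list
#' @return a `peak_list` (see [read_sparky_list()]).
#' @export
read_peaks_csv <- function(input, state = c("free", "bound")) {
  df <- if (length(input) == 1L && file.exists(input)) {
    utils::read.csv(input, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(text = paste(input, collapse = "\n"), stringsAsFactors = FALSE)
  }
  miss <- setdiff(c("assignment", "w1", "w2", "height"), names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  read_sparky_list(sprintf("%s %.17g %.17g %.17g", df$assignment,
                           as.numeric(df$w1), as.numeric(df$w2),
                           as.numeric(df$height)),
                   match.arg(state))
}

#' Write a peak list in Sparky format
#'
#' Shifts and intensities are written with 17 significant digits so a
#' write/read round trip reproduces all numeric fields bit-identically.
#'
#' @param peaks a `peak_list`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sparky_list <- function(peaks, path) {
  tok <- ifelse(peaks$variant == "a", peaks$key, paste0(peaks$key, "_", peaks$variant))
  lines <- c(
    sprintf("%-18s %10s %10s %14s", "Assignment", "w1", "w2", "Height"),
    sprintf("%-18s %.17g %.17g %.17g", tok, peaks$shift_x, peaks$shift_h, peaks$intensity)
  )
  writeLines(lines, path)
  invisible(path)
}

.table_schemas <- list(
  relaxation = list(
    required = c("residue_index", "experiment", "delay_s", "intensity", "replicate"),
    numeric = c("residue_index", "delay_s", "intensity", "replicate")
  ),
  dispersion = list(
    required = c("group", "field_mhz", "nu_cpmg", "intensity", "replicate"),
    numeric = c("field_mhz", "nu_cpmg", "intensity", "replicate")
  ),
  titration = list(
    required = c("protein_nM", "polarization_mP", "replicate"),
    numeric = c("protein_nM", "polarization_mP", "replicate")
  ),
  reporter = list(
    required = c("sample", "abs420", "time_min", "volume_ml", "a600"),
    numeric = c("abs420", "time_min", "volume_ml", "a600")
  )
)

#' Read one of the pipeline's CSV table formats
#'
#' Schemas: `relaxation` (residue_index, experiment = R1|R2, delay_s,
#' intensity, replicate), `dispersion` (group, field_mhz, nu_cpmg with
#' blank meaning the reference spectrum, intensity, replicate),
#' `titration` (protein_nM, polarization_mP, replicate), `reporter`
#' (sample, abs420, time_min, volume_ml, a600). Units are validated:
#' delays in seconds must be non-negative, nu_CPMG in Hz positive
#' (blank = reference), concentrations in nM non-negative.
#'
#' @param input path or character vector of CSV lines.
#' @param schema schema name.
#' @return typed data frame.
#' @export
read_table <- function(input, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  sch <- .table_schemas[[schema]]
  df <- if (length(input) == 1L && file.exists(input)) {
    utils::read.csv(input, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(text = paste(input, collapse = "\n"), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty data section in ", schema, " table", call. = FALSE)
  for (cn in sch$numeric) {
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  }
  if (schema == "relaxation") {
    if (!all(df$experiment %in% c("R1", "R2"))) {
      stop("experiment must be R1 or R2", call. = FALSE)
    }
    if (any(is.na(df$delay_s)) || any(df$delay_s < 0)) {
      stop("negative or missing delay_s", call. = FALSE)
    }
  }
  if (schema == "dispersion") {
    # blank nu_cpmg rows are reference spectra; others must be > 0
    meas <- !is.na(df$nu_cpmg)
    if (any(df$nu_cpmg[meas] <= 0)) stop("nu_cpmg must be positive", call. = FALSE)
    if (!any(meas)) stop("dispersion table has only reference rows", call. = FALSE)
  }
  if (schema == "titration" && any(df$protein_nM < 0, na.rm = TRUE)) {
    stop("protein_nM must be >= 0", call. = FALSE)
  }
  df
}

#' Write an analysis result to JSON
#'
#' Thin convenience wrapper used by all analysis outputs: scalars stay
#' bare numbers (no length-1 arrays) and full numeric precision is
#' kept.
#'
#' @param x list or data frame of results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' TOML-like flat dialect: `key = value` lines, `#` comments, section
#' headers ignored. Values that parse as numbers become numeric;
#' comma-separated values become vectors.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|\\[|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else parts
  }
  out
}
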