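# Intensity tables, proton assignments and 1D spectra.
#
# The analysis pipeline operates on per-proton signed intensities; raw 1D
# spectra are supported only as a convenience front-end (read + integrate).

EXPERIMENT_KINDS <- c("WLOGSY", "STD", "STDOFF", "ONED")

INTENSITY_COLUMNS <- c("ligand_id", "protein_id", "experiment",
                       "protein_present", "mixing_time_s", "proton_id",
                       "intensity")

ASSIGNMENT_COLUMNS <- c("proton_id", "shift_ppm", "window_ppm",
                        "n_equivalent", "is_labile", "near_labile")

#' Create a proton assignment table
#'
#' An assignment describes one ligand proton site: its label, chemical-shift
#' centre, integration half-width, multiplicity, and whether it is an
#' exchangeable (labile, OH/NH-type) proton or sits within 5 Angstrom of one.
#' The labile-proximity flag matters because NOE transfer falls off as
#' 1/r^6, so exchangeable protons contaminate the WaterLOGSY intensities of
#' their close neighbours.
#'
#' @param proton_id Character vector of unique proton labels (e.g. "H1").
#' @param shift_ppm Chemical shift centre of each peak (ppm).
#' @param window_ppm Integration half-width (ppm). `0` selects peak-height
#'   mode in [integrate_peaks()].
#' @param n_equivalent Number of magnetically equivalent protons under each
#'   label (>= 1). Factors are intensity ratios, so equivalent protons are
#'   carried as one assignment whose intensity is the total integral.
#' @param is_labile Logical: exchangeable proton in chemical exchange with
#'   water.
#' @param near_labile Logical: a labile proton lies within 5 Angstrom in the
#'   ligand structure.
#' @return A `data.frame` of class `proton_assignments`.
#' @export
proton_assignments <- function(proton_id, shift_ppm = NA_real_,
                               window_ppm = 0.05, n_equivalent = 1L,
                               is_labile = FALSE, near_labile = FALSE) {
  df <- data.frame(proton_id = as.character(proton_id),
                   shift_ppm = as.numeric(shift_ppm),
                   window_ppm = as.numeric(window_ppm),
                   n_equivalent = as.integer(n_equivalent),
                   is_labile = as.logical(is_labile),
                   near_labile = as.logical(near_labile),
                   stringsAsFactors = FALSE)
  validate_assignments(df)
}

validate_assignments <- function(df) {
  missing <- setdiff(ASSIGNMENT_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_data("assignment table lacks column(s): ",
              paste(missing, collapse = ", "))
  if (anyDuplicated(df$proton_id))
    stop_data("duplicate proton_id in assignments: ",
              paste(unique(df$proton_id[duplicated(df$proton_id)]),
                    collapse = ", "))
  if (any(df$window_ppm < 0)) stop_data("window_ppm must be >= 0")
  if (any(df$n_equivalent < 1L)) stop_data("n_equivalent must be >= 1")
  class(df) <- c("proton_assignments", "data.frame")
  df
}

#' Read a proton assignment table from CSV/TSV
#'
#' Expected columns: `proton_id, shift_ppm, window_ppm, n_equivalent,
#' is_labile, near_labile`.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A `proton_assignments` data frame.
#' @export
read_assignments <- function(path) {
  df <- read_delim_auto(path)
  df$proton_id <- as.character(df$proton_id)
  validate_assignments(df)
}

#' Construct an intensity table
#'
#' The canonical interchange object of the package: signed per-proton peak
#' intensities for one experiment recorded under one condition (with or
#' without protein, at one mixing time). Signs follow the display convention
#' in which protein-mediated transfer from inverted water gives positive
#' WaterLOGSY peaks and free-ligand transfer gives negative peaks.
#'
#' @param intensity Named numeric vector (names = proton ids) or unnamed
#'   numeric with `proton_id` supplied.
#' @param proton_id Proton labels; defaults to `names(intensity)`.
#' @param experiment One of `"WLOGSY"`, `"STD"`, `"STDOFF"`, `"ONED"`.
#' @param protein_present Logical: was the protein receptor in the sample.
#' @param mixing_time_s WaterLOGSY mixing time in seconds (saturation time
#'   for STD, stored in the same slot); must be > 0 for WLOGSY records.
#' @param ligand_id,protein_id Sample identifiers. `protein_id` is empty
#'   when `protein_present` is `FALSE`.
#' @return A `data.frame` of class `intensity_table`.
#' @export
intensity_table <- function(intensity, proton_id = names(intensity),
                            experiment = "WLOGSY", protein_present = FALSE,
                            mixing_time_s = if (identical(experiment, "WLOGSY")) 1.5 else NA_real_,
                            ligand_id = "ligand", protein_id = "") {
  if (is.null(proton_id))
    stop_data("proton_id required (or pass a named intensity vector)")
  df <- data.frame(ligand_id = ligand_id,
                   protein_id = if (isTRUE(protein_present)) protein_id else "",
                   experiment = experiment,
                   protein_present = protein_present,
                   mixing_time_s = as.numeric(mixing_time_s),
                   proton_id = as.character(proton_id),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  validate_intensity_table(df)
}

validate_intensity_table <- function(df) {
  missing <- setdiff(INTENSITY_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_data("intensity table lacks column(s): ",
              paste(missing, collapse = ", "))
  df <- df[INTENSITY_COLUMNS]
  if (nrow(df) == 0) stop_data("intensity table is empty")
  if (!all(df$experiment %in% EXPERIMENT_KINDS))
    stop_data("unknown experiment kind: ",
              paste(setdiff(df$experiment, EXPERIMENT_KINDS), collapse = ", "))
  if (length(unique(df$experiment)) != 1 ||
      length(unique(df$protein_present)) != 1)
    stop_data("an intensity table holds exactly one (experiment, condition)")
  if (length(unique(df$mixing_time_s[!is.na(df$mixing_time_s)])) > 1)
    stop_data("an intensity table holds exactly one mixing time")
  dup <- df$proton_id[duplicated(df$proton_id)]
  if (length(dup) > 0)
    stop_data("duplicate proton ", paste(unique(dup), collapse = ", "),
              " in intensity table")
  if (any(!is.finite(df$intensity)))
    stop_data("non-finite intensity for proton ",
              paste(df$proton_id[!is.finite(df$intensity)], collapse = ", "))
  if (df$experiment[1] == "WLOGSY" &&
      (is.na(df$mixing_time_s[1]) || df$mixing_time_s[1] <= 0))
    stop_data("WLOGSY tables require mixing_time_s > 0")
  class(df) <- c("intensity_table", "data.frame")
  df
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("<intensity_table> %s, %s protein, %d protons",
              x$experiment[1],
              if (x$protein_present[1]) "with" else "without", nrow(x)))
  if (!is.na(x$mixing_time_s[1]))
    cat(sprintf(", tau_mix = %g s", x$mixing_time_s[1]))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Named intensity lookup preserving the table's proton order.
intensities_of <- function(tbl, protons = tbl$proton_id) {
  idx <- match(protons, tbl$proton_id)
  if (anyNA(idx))
    stop_data("missing proton ", paste(protons[is.na(idx)], collapse = ", "))
  stats::setNames(tbl$intensity[idx], protons)
}

#' Read an intensity table from CSV/TSV
#'
#' Columns: `ligand_id, protein_id, experiment, protein_present,
#' mixing_time_s, proton_id, intensity`. Signed values are preserved
#' exactly. When `assignments` is supplied every assigned proton must be
#' present.
#'
#' @param path File path (delimiter from extension).
#' @param assignments Optional `proton_assignments` to validate coverage.
#' @return An `intensity_table`.
#' @export
read_intensity_table <- function(path, assignments = NULL) {
  df <- read_delim_auto(path, colClasses = "character")
  missing <- setdiff(INTENSITY_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_data("intensity table lacks column(s): ",
              paste(missing, collapse = ", "))
  inten <- suppressWarnings(as.numeric(df$intensity))
  bad <- is.na(inten) & !is.na(df$intensity)
  if (any(bad))
    stop_data("non-numeric intensity for proton ",
              paste(df$proton_id[bad], collapse = ", "))
  df$intensity <- inten
  df$mixing_time_s <- suppressWarnings(as.numeric(df$mixing_time_s))
  df$protein_present <- as.logical(df$protein_present)
  tbl <- validate_intensity_table(df)
  if (!is.null(assignments)) {
    absent <- setdiff(assignments$proton_id, tbl$proton_id)
    if (length(absent) > 0)
      stop_data("missing proton ", paste(absent, collapse = ", "))
  }
  tbl
}

#' Write an intensity table to CSV/TSV
#'
#' @param tbl An `intensity_table`.
#' @param path Output path (delimiter from extension).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "intensity_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(tbl)
  # full precision so read -> write -> read is bit-exact
  df$intensity <- sprintf("%.17g", df$intensity)
  df$mixing_time_s <- ifelse(is.na(df$mixing_time_s), "",
                             sprintf("%.17g", df$mixing_time_s))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path, ...) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, ...)
}

#' Construct a 1D spectrum
#'
#' @param ppm Chemical-shift axis; stored strictly ascending (descending
#'   input is reversed together with the values).
#' @param values Signed intensities, same length as `ppm`.
#' @param metadata Optional list (field MHz, temperature, experiment tag).
#' @return A list of class `spectrum1d` with elements `ppm`, `values`,
#'   `metadata`.
#' @export
spectrum1d <- function(ppm, values, metadata = list()) {
  ppm <- as.numeric(ppm); values <- as.numeric(values)
  if (length(ppm) != length(values))
    stop_data("ppm axis and values differ in length")
  d <- diff(ppm)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop_data("ppm axis must be strictly monotone")
  if (length(d) > 0 && d[1] < 0) {  # store ascending
    ppm <- rev(ppm); values <- rev(values)
  }
  structure(list(ppm = ppm, values = values, metadata = metadata),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.3f..%.3f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read a 1D spectrum
#'
#' Supports minimal real-1D JCAMP-DX (AFFN-encoded `XYDATA=(X++(Y..Y))` or
#' `XYPOINTS=(XY..XY)`) and plain two-column ppm/intensity text
#' (whitespace- or comma-separated). Compound/multi-block and 2D JCAMP
#' files are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/content), `"jcampdx"` or `"xy"`.
#' @return A [spectrum1d()] with ascending ppm axis.
#' @export
read_spectrum <- function(path, format = c("auto", "jcampdx", "xy")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", path, ignore.case = TRUE))
      "jcampdx"
    else {
      head1 <- readLines(path, n = 1L, warn = FALSE)
      if (length(head1) > 0 && grepl("^##", head1)) "jcampdx" else "xy"
    }
  }
  if (format == "jcampdx") read_jcampdx(path) else read_xy(path)
}

read_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "[,;[:space:]]+")
  n <- vapply(toks, length, 1L)
  if (any(n != 2))
    stop_data("two-column ppm,intensity file expected: line with ",
              n[n != 2][1], " fields found")
  m <- vapply(toks, function(t) as.numeric(t), numeric(2))
  spectrum1d(m[1, ], m[2, ], metadata = list(source = basename(path)))
}

read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^##END=", lines)
  titles <- grep("^##TITLE=", lines)
  if (length(ends) > 1 || length(titles) > 1 ||
      any(grepl("^##BLOCKS=", lines)) || any(grepl("^##NTUPLES=", lines)))
    stop_data("unsupported JCAMP-DX file: compound/multi-block or nD data")
  getfield <- function(key) {
    i <- grep(paste0("^##", key, "="), lines)
    if (length(i) == 0) return(NA_character_)
    sub(paste0("^##", key, "=\\s*"), "", lines[i[1]])
  }
  num <- function(key) suppressWarnings(as.numeric(getfield(key)))
  meta <- list(title = getfield("TITLE"),
               field_mhz = num("\\.OBSERVE FREQUENCY"),
               xunits = getfield("XUNITS"))
  xf <- num("XFACTOR"); if (is.na(xf)) xf <- 1
  yf <- num("YFACTOR"); if (is.na(yf)) yf <- 1
  ix <- grep("^##XYDATA=", lines)
  ip <- grep("^##XYPOINTS=", lines)
  stopnum <- function(v, what)
    if (any(is.na(v))) stop_data("malformed JCAMP-DX numeric data (", what, ")")
  if (length(ix) == 1) {
    spec <- getfield("XYDATA")
    if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", spec))
      stop_data("unsupported JCAMP-DX XYDATA variant: ", spec)
    end <- if (length(ends) == 1) ends[1] else length(lines) + 1L
    body <- lines[seq(ix + 1L, end - 1L)]
    if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body))))
      stop_data("compressed (SQZ/DIF/DUP) JCAMP-DX is not supported; use AFFN")
    x <- numeric(0); y <- numeric(0)
    for (ln in body) {
      v <- as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1]])
      stopnum(v, "XYDATA line")
      if (length(v) < 2) next
      x <- c(x, v[1]); y <- c(y, v[-1])
      # per-line first value is the x of the first y; remaining x implied
    }
    npt <- num("NPOINTS"); firstx <- num("FIRSTX"); lastx <- num("LASTX")
    if (is.na(npt)) npt <- length(y)
    if (length(y) != npt)
      stop_data("JCAMP-DX NPOINTS (", npt, ") != values read (", length(y), ")")
    if (is.na(firstx)) firstx <- x[1] * xf
    if (is.na(lastx)) lastx <- firstx
    ppm <- seq(firstx, lastx, length.out = npt)
    spectrum1d(ppm, y * yf, metadata = meta)
  } else if (length(ip) == 1) {
    end <- if (length(ends) == 1) ends[1] else length(lines) + 1L
    body <- lines[seq(ip + 1L, end - 1L)]
    v <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    stopnum(v, "XYPOINTS")
    if (length(v) %% 2 != 0) stop_data("odd value count in XYPOINTS block")
    m <- matrix(v, nrow = 2)
    spectrum1d(m[1, ] * xf, m[2, ] * yf, metadata = meta)
  } else {
    stop_data("no XYDATA/XYPOINTS block found in JCAMP-DX file")
  }
}

#' Write a 1D spectrum as minimal JCAMP-DX
#'
#' Emits an AFFN `XYDATA=(X++(Y..Y))` block on an evenly spaced axis (the
#' spectrum is written point-by-point; an uneven axis is rejected).
#'
#' @param spec A [spectrum1d()].
#' @param path Output path.
#' @param title Spectrum title record.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spec, path, title = "waterlogsy export") {
  stopifnot(inherits(spec, "spectrum1d"))
  d <- diff(spec$ppm)
  if (length(d) > 1 && diff(range(d)) > 1e-9 * max(abs(d)))
    stop_data("JCAMP-DX export requires an evenly spaced ppm axis")
  n <- length(spec$ppm)
  hdr <- c(paste0("##TITLE=", title),
           "##JCAMP-DX=4.24",
           "##DATA TYPE=NMR SPECTRUM",
           "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
           "##XFACTOR=1", "##YFACTOR=1",
           sprintf("##FIRSTX=%.10g", spec$ppm[1]),
           sprintf("##LASTX=%.10g", spec$ppm[n]),
           sprintf("##NPOINTS=%d", n),
           "##XYDATA=(X++(Y..Y))")
  idx <- split(seq_len(n), ceiling(seq_len(n) / 6))
  body <- vapply(idx, function(i) {
    paste(c(sprintf("%.10g", spec$ppm[i[1]]),
            sprintf("%.10g", spec$values[i])), collapse = " ")
  }, character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Integrate assigned peaks of a 1D spectrum into an intensity table
#'
#' Signed trapezoidal integration over the closed window
#' `[shift - window, shift + window]` per assignment, with an optional
#' linear baseline anchored at the window edges. An assignment with
#' `window_ppm = 0` yields the interpolated peak height instead of an
#' integral. Overlapping windows are recorded as a warning in the table's
#' `"integration_warnings"` attribute.
#'
#' @param spec A [spectrum1d()].
#' @param assignments A [proton_assignments()] table.
#' @param baseline `"none"` or `"linear"` (edge-anchored).
#' @param experiment,protein_present,mixing_time_s,ligand_id,protein_id
#'   Condition metadata for the resulting [intensity_table()].
#' @return An `intensity_table` with one record per assignment.
#' @export
integrate_peaks <- function(spec, assignments, baseline = c("none", "linear"),
                            experiment = "WLOGSY", protein_present = FALSE,
                            mixing_time_s = if (identical(experiment, "WLOGSY")) 1.5 else NA_real_,
                            ligand_id = "ligand", protein_id = "") {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spec, "spectrum1d"))
  assignments <- validate_assignments(as.data.frame(assignments))
  lo <- assignments$shift_ppm - assignments$window_ppm
  hi <- assignments$shift_ppm + assignments$window_ppm
  rng <- range(spec$ppm)
  out <- any(lo < rng[1] | hi > rng[2])
  if (out)
    stop_data("integration window outside spectrum axis for proton ",
              paste(assignments$proton_id[lo < rng[1] | hi > rng[2]],
                    collapse = ", "))
  warnings <- character(0)
  ord <- order(lo)
  if (nrow(assignments) > 1) {
    over <- which(hi[ord][-length(ord)] > lo[ord][-1])
    if (length(over) > 0) {
      pairs <- paste(assignments$proton_id[ord][over],
                     assignments$proton_id[ord][over + 1], sep = "/")
      warnings <- c(warnings,
                    paste0("overlapping windows: ",
                           paste(pairs, collapse = ", ")))
      warning("overlapping integration windows: ",
              paste(pairs, collapse = ", "), call. = FALSE)
    }
  }
  value_at <- function(x) stats::approx(spec$ppm, spec$values, xout = x,
                                        rule = 1)$y
  vals <- vapply(seq_len(nrow(assignments)), function(i) {
    if (assignments$window_ppm[i] == 0) return(value_at(assignments$shift_ppm[i]))
    inside <- spec$ppm > lo[i] & spec$ppm < hi[i]
    xs <- c(lo[i], spec$ppm[inside], hi[i])
    ys <- c(value_at(lo[i]), spec$values[inside], value_at(hi[i]))
    if (baseline == "linear") {
      base <- ys[1] + (ys[length(ys)] - ys[1]) * (xs - xs[1]) /
        (xs[length(xs)] - xs[1])
      ys <- ys - base
    }
    trapz(xs, ys)
  }, numeric(1))
  tbl <- intensity_table(vals, proton_id = assignments$proton_id,
                         experiment = experiment,
                         protein_present = protein_present,
                         mixing_time_s = mixing_time_s,
                         ligand_id = ligand_id, protein_id = protein_id)
  attr(tbl, "integration_warnings") <- warnings
  tbl
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
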