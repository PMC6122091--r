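#' @include spectra-core.R
NULL

.read_text_lines <- function(x) {
  ## accept a file path or a character vector of lines; normalize CRLF
  if (length(x) == 1 && file.exists(x)) x <- readLines(x, warn = FALSE)
  sub("\r$", "", x)
}

#' Parse excited states from a quantum-chemistry TDDFT log
#'
#' Reads the mainstream Gaussian-type output dialect: per-state
#' `Excited State N: <spin-sym> <E> eV <lambda> nm f=<f>` lines and the
#' length-gauge rotatory-strength table (the section whose header names
#' `R(length)`).  Energies are taken from the eV field; when the printed nm
#' value disagrees with hc/E by more than 0.1 nm a warning is issued (the
#' eV value wins).  When spin labels are present only singlet states are
#' retained.  Every retained state must appear in the R(length) table;
#' missing entries are an error, never a silent zero.
#'
#' @param x path to a log file, or a character vector of its lines.
#' @param label spectrum label (defaults to the file name when `x` is a
#'   path).
#' @return a [StickSpectrum-class].
#' @export
parseQcLog <- function(x, label = NULL) {
  if (is.null(label))
    label <- if (length(x) == 1 && file.exists(x)) basename(x) else NA_character_
  lines <- .read_text_lines(x)

  es_re <- paste0("^\\s*Excited State\\s+(\\d+):\\s+(\\S+)\\s+",
                  "(-?[0-9.]+)\\s*eV\\s+(-?[0-9.]+)\\s*nm",
                  "(?:\\s+f=\\s*(-?[0-9.]+))?")
  es_idx <- grep(es_re, lines, perl = TRUE)
  if (length(es_idx) == 0)
    stop("format error: no 'Excited State' block found in input")
  m <- regmatches(lines[es_idx], regexec(es_re, lines[es_idx], perl = TRUE))
  es <- do.call(rbind, lapply(m, function(g)
    data.frame(index = as.integer(g[2]), spin = g[3],
               energy_eV = as.numeric(g[4]), nm = as.numeric(g[5]),
               f = ifelse(g[6] == "", NA_real_, suppressWarnings(as.numeric(g[6]))))))

  ## keep singlets when multiplicity labels are present
  has_labels <- any(grepl("^(Singlet|Triplet)", es$spin))
  if (has_labels) es <- es[grepl("^Singlet", es$spin), , drop = FALSE]
  if (nrow(es) == 0)
    stop("format error: no singlet excited states found")

  mismatch <- abs(HC_EV_NM / es$energy_eV - es$nm) > 0.1
  if (any(mismatch))
    warning("energy/wavelength mismatch (> 0.1 nm) for state(s) ",
            paste(es$index[mismatch], collapse = ", "),
            "; using the eV values")

  ## locate the R(length) rotatory-strength table
  rl_head <- grep("R\\(length\\)", lines)
  if (length(rl_head) == 0)
    stop("format error: no 'R(length)' rotatory-strength section found")
  row_re <- "^\\s*(\\d+)((\\s+-?[0-9.]+(?:[DdEe][+-]?\\d+)?){4})\\s*$"
  rvals <- c()
  i <- rl_head[1] + 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl(row_re, ln)) {
      g <- regmatches(ln, regexec(row_re, ln))[[1]]
      nums <- as.numeric(strsplit(trimws(g[3]), "\\s+")[[1]])
      rvals[as.character(as.integer(g[2]))] <- nums[4]  # XX YY ZZ R(length)
    } else if (!grepl("^\\s*$", ln) && length(rvals) > 0) {
      break  # table ended
    }
    i <- i + 1
  }
  if (length(rvals) == 0)
    stop("format error: 'R(length)' section contains no parseable rows")

  missing <- setdiff(as.character(es$index), names(rvals))
  if (length(missing) > 0)
    stop("state count mismatch: ", nrow(es), " excited state(s) but ",
         length(rvals), " R(length) row(s); missing state(s) ",
         paste(missing, collapse = ", "))

  StickSpectrum(energies = es$energy_eV,
                rotatoryStrengths = as.numeric(rvals[as.character(es$index)]),
                oscillatorStrengths = es$f, indices = es$index,
                label = label, metadata = list(source = "qc_log"))
}

.stick_header <- c("state", "energy_eV", "wavelength_nm",
                   "R_length_1e-40cgs", "f")

#' Read and write the stick-spectrum exchange table
#'
#' The exchange format is a tab- (or comma-) separated table with header
#' `state  energy_eV  wavelength_nm  R_length_1e-40cgs  f`.  The energy
#' column is authoritative; a wavelength disagreeing with hc/E by more than
#' 0.1 nm triggers a warning.  `writeStickTable()` followed by
#' `readStickTable()` reproduces all values to better than 1e-12.
#'
#' @param path file path.
#' @param label spectrum label (default: file name).
#' @return `readStickTable()` returns a [StickSpectrum-class];
#'   `writeStickTable()` returns `path` invisibly.
#' @export
readStickTable <- function(path, label = basename(path)) {
  lines <- .read_text_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) stop("empty stick table: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep)[[1]])
  if (length(header) < 4 || header[1] != "state")
    stop("stick table must start with a header line 'state", sep,
         "energy_eV", sep, "...'")
  rows <- lines[-1]
  n <- length(rows)
  out <- data.frame(index = integer(n), energy_eV = numeric(n),
                    nm = numeric(n), R = numeric(n), f = numeric(n))
  for (k in seq_len(n)) {
    fields <- suppressWarnings(as.numeric(trimws(strsplit(rows[k], sep)[[1]])))
    if (length(fields) < 4 || any(is.na(fields[1:4])))
      stop("unparseable stick-table row at line ", k + 1, " of ", path)
    if (fields[2] <= 0)
      stop("non-positive energy at line ", k + 1, " of ", path)
    out$index[k] <- as.integer(fields[1])
    out$energy_eV[k] <- fields[2]
    out$nm[k] <- fields[3]
    out$R[k] <- fields[4]
    out$f[k] <- if (length(fields) >= 5) fields[5] else NA_real_
  }
  if (n > 0) {
    mismatch <- abs(HC_EV_NM / out$energy_eV - out$nm) > 0.1
    if (any(mismatch))
      warning("energy/wavelength mismatch (> 0.1 nm) at line(s) ",
              paste(which(mismatch) + 1, collapse = ", "),
              "; using the eV values")
  }
  StickSpectrum(energies = out$energy_eV, rotatoryStrengths = out$R,
                oscillatorStrengths = out$f, indices = out$index,
                label = label, metadata = list(source = path))
}

#' @param stick a [StickSpectrum-class] to write.
#' @rdname readStickTable
#' @export
writeStickTable <- function(stick, path) {
  stopifnot(is(stick, "StickSpectrum"))
  st <- stick@states
  lines <- paste(.stick_header, collapse = "\t")
  if (nrow(st) > 0) {
    lines <- c(lines, sprintf("%d\t%.17g\t%.17g\t%.17g\t%s",
                              st$index, st$energy_eV,
                              HC_EV_NM / st$energy_eV, st$rotatory_strength,
                              ifelse(is.na(st$oscillator_strength), "NA",
                                     sprintf("%.17g",
                                             st$oscillator_strength))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an experimental ECD spectrum from CSV
#'
#' Two numeric columns (wavelength in nm, Delta-epsilon in M^-1 cm^-1) with
#' an optional header.  Rows are sorted by wavelength; duplicate wavelengths
#' are averaged.  Fewer than 3 valid rows is an error.
#'
#' @param path CSV file path.
#' @param label spectrum label (default: file name).
#' @return a [CDSpectrum-class] tagged with `metadata$source`.
#' @export
readExperimentalCsv <- function(path, label = basename(path)) {
  lines <- .read_text_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  parsed <- lapply(lines, function(ln) {
    suppressWarnings(as.numeric(trimws(strsplit(ln, ",")[[1]])))
  })
  ok <- vapply(parsed, function(v) length(v) >= 2 && !any(is.na(v[1:2])),
               logical(1))
  rows <- do.call(rbind, lapply(parsed[ok], function(v) v[1:2]))
  if (is.null(rows) || nrow(rows) < 3)
    stop("insufficient data: experimental spectrum needs >= 3 valid rows, ",
         "found ", if (is.null(rows)) 0 else nrow(rows))
  agg <- stats::aggregate(list(value = rows[, 2]),
                          by = list(nm = rows[, 1]), FUN = mean)
  agg <- agg[order(agg$nm), ]
  CDSpectrum(grid = agg$nm, values = agg$value, axis = "wavelength_nm",
             label = label, metadata = list(source = path,
                                            kind = "experimental"))
}
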