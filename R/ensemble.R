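#' @include qc-io.R
NULL

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation via [stats::approx()].  The target grid must lie
#' within the span of the source grid; extrapolation is refused.
#'
#' @param spectrum a [CDSpectrum-class] on a wavelength axis.
#' @param grid target wavelengths (nm), increasing.
#' @return a [CDSpectrum-class] on `grid`.
#' @export
resampleSpectrum <- function(spectrum, grid) {
  stopifnot(is(spectrum, "CDSpectrum"))
  if (spectrum@axis != "wavelength_nm")
    stop("resampleSpectrum expects a wavelength-axis spectrum")
  src <- spectrum@grid
  if (min(grid) < min(src) || max(grid) > max(src))
    stop(sprintf(
      "range error: target grid [%g, %g] exceeds source span [%g, %g] nm",
      min(grid), max(grid), min(src), max(src)))
  if (identical(as.numeric(grid), as.numeric(src))) return(spectrum)
  vals <- stats::approx(src, spectrum@values, xout = grid)$y
  CDSpectrum(grid = grid, values = vals, axis = "wavelength_nm",
             label = spectrum@label, metadata = spectrum@metadata)
}

.common_grid <- function(spectra) {
  lo <- max(vapply(spectra, function(s) min(s@grid), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s@grid), numeric(1)))
  if (lo >= hi)
    stop("member spectra have no overlapping wavelength span")
  step <- min(vapply(spectra, function(s)
    if (length(s@grid) > 1) stats::median(diff(s@grid)) else hi - lo,
    numeric(1)))
  seq(lo, hi, by = step)
}

#' Average snapshot spectra with a pointwise confidence band
#'
#' Members are first resampled to a common grid (the intersection of their
#' spans at the finest member step, so no extrapolation occurs), then
#' averaged pointwise.  The confidence band of the mean is either the
#' Student-t interval mean +/- t_{(1-cl)/2, n-1} * s/sqrt(n) with s the
#' pointwise sample standard deviation (default; appropriate for the small
#' snapshot counts, typically ten, used in ensemble ECD work), or a seeded
#' bootstrap percentile interval over member resamples.
#'
#' With a single member the band degenerates to the mean and a warning is
#' issued.
#'
#' @param spectra list of [CDSpectrum-class] members (>= 1).
#' @param confidenceLevel fraction, default 0.95.
#' @param method `"t"` or `"bootstrap"`.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap stream.
#' @return an [EnsembleSpectrum-class].
#' @examples
#' st <- StickSpectrum(c(4.5, 5.9), c(-15, -25))
#' sp <- convolveSticks(st)
#' ens <- averageSpectra(list(sp, sp, sp))
#' nMembers(ens)
#' @export
averageSpectra <- function(spectra, confidenceLevel = 0.95,
                           method = c("t", "bootstrap"), nBoot = 2000,
                           seed = 1) {
  method <- match.arg(method)
  if (length(spectra) == 0) stop("cannot average an empty ensemble")
  stopifnot(all(vapply(spectra, is, logical(1), "CDSpectrum")))
  grids <- lapply(spectra, function(s) s@grid)
  if (all(vapply(grids, identical, logical(1), grids[[1]]))) {
    grid <- grids[[1]]
  } else {
    grid <- .common_grid(spectra)
    spectra <- lapply(spectra, resampleSpectrum, grid = grid)
  }
  n <- length(spectra)
  M <- vapply(spectra, function(s) s@values, numeric(length(grid)))
  M <- matrix(M, nrow = length(grid), ncol = n)
  mu <- rowMeans(M)
  if (n == 1) {
    warning("single-member ensemble: confidence band degenerates to the mean")
    lo <- hi <- mu
  } else if (method == "t") {
    s <- apply(M, 1, stats::sd)
    half <- stats::qt(1 - (1 - confidenceLevel) / 2, df = n - 1) * s / sqrt(n)
    lo <- mu - half
    hi <- mu + half
  } else {
    set.seed(seed)
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
    boot_means <- apply(idx, 1, function(i) rowMeans(M[, i, drop = FALSE]))
    qs <- apply(boot_means, 1, stats::quantile,
                probs = c((1 - confidenceLevel) / 2,
                          1 - (1 - confidenceLevel) / 2))
    ## percentile band can sit on one side of the mean for skewed draws;
    ## widen minimally so the band always brackets the mean
    lo <- pmin(qs[1, ], mu)
    hi <- pmax(qs[2, ], mu)
  }
  new("EnsembleSpectrum", grid = grid, mean = mu, ciLower = lo, ciUpper = hi,
      members = spectra, confidenceLevel = confidenceLevel, ciMethod = method)
}

#' Write an ensemble spectrum as CSV
#'
#' Columns: `wavelength_nm, mean, ci_lower, ci_upper, member_1..member_n`.
#' Numbers are formatted deterministically so identical ensembles produce
#' byte-identical files.
#'
#' @param ensemble an [EnsembleSpectrum-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEnsembleCsv <- function(ensemble, path) {
  stopifnot(is(ensemble, "EnsembleSpectrum"))
  n <- nMembers(ensemble)
  header <- paste(c("wavelength_nm", "mean", "ci_lower", "ci_upper",
                    paste0("member_", seq_len(n))), collapse = ",")
  M <- vapply(ensemble@members, function(s) s@values,
              numeric(length(ensemble@grid)))
  M <- matrix(M, nrow = length(ensemble@grid), ncol = n)
  body <- apply(cbind(ensemble@grid, ensemble@mean, ensemble@ciLower,
                      ensemble@ciUpper, M), 1,
                function(r) paste(sprintf("%.15g", r), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back an ensemble CSV written by [writeEnsembleCsv()]
#'
#' @param path CSV path.
#' @return an [EnsembleSpectrum-class] (ciMethod recorded as "t").
#' @export
readEnsembleCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  member_cols <- grep("^member_", names(df), value = TRUE)
  members <- lapply(seq_along(member_cols), function(i)
    CDSpectrum(df$wavelength_nm, df[[member_cols[i]]],
               label = member_cols[i]))
  new("EnsembleSpectrum", grid = df$wavelength_nm, mean = df$mean,
      ciLower = df$ci_lower, ciUpper = df$ci_upper, members = members,
      confidenceLevel = 0.95, ciMethod = "t")
}
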