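#' @include ensemble.R
NULL

## Local maxima indices of v (first point of a plateau); interior only.
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L  # walk plateau
      if (j < n && v[j + 1L] < v[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

## Topographic prominence of the maximum of v at index i: height minus the
## higher of the lowest points separating it from higher terrain (or the
## boundary) on each side.
.prominence <- function(v, i) {
  h <- v[i]
  left <- v[seq_len(i - 1L)]
  right <- v[seq.int(i + 1L, length(v))]
  left_key <- {
    higher <- which(left > h)
    if (length(higher) == 0) min(left) else min(left[(max(higher) + 1):length(left)])
  }
  right_key <- {
    higher <- which(right > h)
    if (length(higher) == 0) min(right) else min(right[seq_len(min(higher) - 1)])
  }
  h - max(left_key, right_key)
}

#' Detect peaks in a CD spectrum
#'
#' Finds local extrema by topographic prominence: local maxima with positive
#' amplitude are reported as positive peaks, local minima with negative
#' amplitude as negative peaks (the sign convention of ECD band language).
#' Extrema with prominence below `minProminence` are suppressed, which
#' filters grid-level noise without thresholding genuine shoulders.  Peak
#' positions are grid-resolution quantities: the position is the grid point
#' of the extremum, with optional parabolic sub-grid refinement.
#'
#' @param spectrum a [CDSpectrum-class] with at least 3 points.
#' @param minProminence prominence floor in M^-1 cm^-1 (default 1).
#' @param refine logical; parabolic 3-point refinement of positions
#'   (default FALSE).
#' @return data.frame with columns `position_nm`, `amplitude`, `sign`
#'   (`"positive"`/`"negative"`), `prominence`, sorted by position.
#' @examples
#' st <- StickSpectrum(c(4.51, 5.90), c(-15, -25))
#' findPeaks(convolveSticks(st))
#' @export
findPeaks <- function(spectrum, minProminence = 1, refine = FALSE) {
  stopifnot(is(spectrum, "CDSpectrum"))
  v <- spectrum@values
  g <- spectrum@grid
  if (length(v) < 3)
    stop("spectrum too short for peak detection (need >= 3 points)")
  one_sign <- function(w, sgn) {
    idx <- .local_maxima(w)
    if (length(idx) == 0) return(NULL)
    prom <- vapply(idx, function(i) .prominence(w, i), numeric(1))
    keep <- prom >= minProminence & sgn * v[idx] > 0
    idx <- idx[keep]; prom <- prom[keep]
    if (length(idx) == 0) return(NULL)
    pos <- g[idx]
    if (refine) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (i > 1 && i < length(w)) {
          d <- (w[i - 1] - w[i + 1]) / (2 * (w[i - 1] - 2 * w[i] + w[i + 1]))
          if (is.finite(d) && abs(d) <= 1) pos[k] <- g[i] + d * (g[i + 1] - g[i])
        }
      }
    }
    data.frame(position_nm = pos, amplitude = v[idx],
               sign = if (sgn > 0) "positive" else "negative",
               prominence = prom)
  }
  out <- rbind(one_sign(v, +1), one_sign(-v, -1))
  if (is.null(out))
    out <- data.frame(position_nm = numeric(), amplitude = numeric(),
                      sign = character(), prominence = numeric())
  out <- out[order(out$position_nm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match calculated against experimental peaks and measure shifts
#'
#' After filtering both peak sets to `signFilter`, pairs are formed by
#' greedy nearest-position matching without replacement (smallest absolute
#' shift first; ties broken toward the shorter-wavelength pair, so reports
#' are deterministic).  The per-pair shift is calc - exp in nm.  The verdict
#' is TRUE iff every matched absolute shift is within `toleranceNm`
#' (default 20 nm, the conventional agreement window for ECD peak
#' positions).
#'
#' @param calcPeaks,expPeaks peak data.frames from [findPeaks()], or numeric
#'   vectors of peak positions in nm.
#' @param signFilter `"negative"` (default), `"positive"` or `"both"`.
#' @param toleranceNm verdict tolerance in nm.
#' @return a [ComparisonReport-class].
#' @examples
#' matchPeaks(c(-200, -270), c(-220, -280))  # negative peaks by position
#' @export
matchPeaks <- function(calcPeaks, expPeaks,
                       signFilter = c("negative", "positive", "both"),
                       toleranceNm = 20) {
  signFilter <- match.arg(signFilter)
  as_peaks <- function(x) {
    if (is.numeric(x))
      return(data.frame(position_nm = abs(x),
                        amplitude = ifelse(x < 0, -1, 1),
                        sign = ifelse(x < 0, "negative", "positive"),
                        prominence = NA_real_))
    x
  }
  cp <- as_peaks(calcPeaks); ep <- as_peaks(expPeaks)
  if (signFilter != "both") {
    cp <- cp[cp$sign == signFilter, , drop = FALSE]
    ep <- ep[ep$sign == signFilter, , drop = FALSE]
  }
  if (nrow(cp) == 0)
    stop("no calculated peaks remain after the '", signFilter,
         "' sign filter")
  if (nrow(ep) == 0)
    stop("no experimental peaks remain after the '", signFilter,
         "' sign filter")
  ## greedy nearest matching without replacement
  cand <- expand.grid(ci = seq_len(nrow(cp)), ei = seq_len(nrow(ep)))
  cand$dist <- abs(cp$position_nm[cand$ci] - ep$position_nm[cand$ei])
  cand$tie <- pmin(cp$position_nm[cand$ci], ep$position_nm[cand$ei])
  cand <- cand[order(cand$dist, cand$tie), , drop = FALSE]
  used_c <- logical(nrow(cp)); used_e <- logical(nrow(ep))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ci <- cand$ci[k]; ei <- cand$ei[k]
    if (!used_c[ci] && !used_e[ei]) {
      used_c[ci] <- TRUE; used_e[ei] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(
        calc_nm = cp$position_nm[ci], exp_nm = ep$position_nm[ei],
        shift_nm = cp$position_nm[ci] - ep$position_nm[ei],
        calc_amplitude = cp$amplitude[ci], exp_amplitude = ep$amplitude[ei])
    }
  }
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$calc_nm), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ComparisonReport", pairs = pairs,
      unmatchedCalc = cp[!used_c, , drop = FALSE],
      unmatchedExp = ep[!used_e, , drop = FALSE],
      maxAbsShift = max(abs(pairs$shift_nm)), toleranceNm = toleranceNm,
      verdict = all(abs(pairs$shift_nm) <= toleranceNm),
      signFilter = signFilter)
}

#' Maximum positive CD amplitude in a wavelength window
#'
#' The spurious-shoulder diagnostic: returns max(0, max Delta-epsilon) over
#' the grid points falling in `window` (default 220-240 nm, where spurious
#' positive shoulders appear in over-exact-exchange ECD predictions of
#' silver-mediated guanine duplexes).  An everywhere-negative spectrum
#' yields exactly 0.
#'
#' @param spectrum a [CDSpectrum-class] on a wavelength axis.
#' @param window length-2 nm interval; must overlap the grid.
#' @return maximum positive Delta-epsilon in the window (0 if none).
#' @export
positiveFeature <- function(spectrum, window = c(220, 240)) {
  stopifnot(is(spectrum, "CDSpectrum"), length(window) == 2)
  g <- spectrum@grid
  sel <- g >= min(window) & g <= max(window)
  if (!any(sel))
    stop(sprintf("range error: window [%g, %g] nm is disjoint from the grid",
                 min(window), max(window)))
  max(0, max(spectrum@values[sel]))
}

#' Attach the positive-feature diagnostic to a comparison report
#'
#' @param report a [ComparisonReport-class].
#' @param spectrum the calculated [CDSpectrum-class].
#' @param window nm window, default 220-240.
#' @return the report with `positiveFeature`/`positiveWindow` filled in.
#' @export
addPositiveFeature <- function(report, spectrum, window = c(220, 240)) {
  report@positiveFeature <- positiveFeature(spectrum, window)
  report@positiveWindow <- as.numeric(window)
  report
}

#' Serialize a comparison report
#'
#' `writeComparisonReport()` writes a flat key-value text file;
#' `writeMatchedPairsCsv()` writes the matched-pair table as CSV.
#'
#' @param report a [ComparisonReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeComparisonReport <- function(report, path) {
  kv <- c(sprintf("sign_filter: %s", report@signFilter),
          sprintf("n_matched: %d", nrow(report@pairs)),
          sprintf("n_unmatched_calc: %d", nrow(report@unmatchedCalc)),
          sprintf("n_unmatched_exp: %d", nrow(report@unmatchedExp)),
          sprintf("max_abs_shift_nm: %.10g", report@maxAbsShift),
          sprintf("tolerance_nm: %.10g", report@toleranceNm),
          sprintf("all_peaks_within_tolerance: %s", report@verdict))
  if (!is.na(report@positiveFeature))
    kv <- c(kv, sprintf("positive_feature_window_nm: %.10g-%.10g",
                        report@positiveWindow[1], report@positiveWindow[2]),
            sprintf("positive_feature_max: %.10g", report@positiveFeature))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname writeComparisonReport
#' @export
writeMatchedPairsCsv <- function(report, path) {
  p <- report@pairs
  lines <- c("calc_nm,exp_nm,shift_nm,calc_amplitude,exp_amplitude",
             sprintf("%.10g,%.10g,%.10g,%.10g,%.10g", p$calc_nm, p$exp_nm,
                     p$shift_nm, p$calc_amplitude, p$exp_amplitude))
  writeLines(lines, path)
  invisible(path)
}
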