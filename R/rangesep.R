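#' @include methods.R
NULL

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Standard Coulomb-attenuation parameter sets
#'
#' `camB3LYP()` returns the CAM-B3LYP defaults (alpha = 0.19, beta = 0.46,
#' mu = 0.33 bohr^-1); `b3lyp()` returns the parameters that reduce the
#' attenuated form to the global hybrid B3LYP (alpha = 0.20, beta = 0,
#' mu kept at 0.33 -- with beta = 0 the value of mu is immaterial).
#'
#' @return a [RangeSepParams-class].
#' @export
camB3LYP <- function() RangeSepParams(0.19, 0.46, 0.33)

#' @rdname camB3LYP
#' @export
b3lyp <- function() RangeSepParams(0.20, 0, 0.33)

#' Hartree-Fock exchange weight at interelectronic distance r12
#'
#' For a Coulomb-attenuated hybrid, the HF-exchange fraction is
#' alpha + beta * erf(mu * r12): alpha at r12 = 0, alpha + beta in the
#' long-range limit.  The complementary DFT-exchange weight is one minus
#' this.
#'
#' @param r12 interelectronic distance in bohr (>= 0); vectorized.
#' @param p a [RangeSepParams-class].
#' @return dimensionless weight(s) in \[0, 1\].
#' @examples
#' hfWeight(0, camB3LYP())     # 0.19
#' hfWeight(1e6, camB3LYP())   # ~0.65
#' @export
hfWeight <- function(r12, p) {
  stopifnot(is(p, "RangeSepParams"))
  validObject(p)
  if (any(r12 < 0)) stop("r12 must be >= 0 (bohr)")
  p@alpha + p@beta * .erf(p@mu * r12)
}

#' @rdname hfWeight
#' @export
dftWeight <- function(r12, p) 1 - hfWeight(r12, p)

#' Linear interpolation path between two range-separation parameter sets
#'
#' Generates `nPoints` parameter sets at equally spaced fractions t in
#' \[0, 1\], interpolating alpha and beta linearly while holding mu at the
#' start value (the attenuation midpoint is conventionally kept fixed when
#' morphing CAM-B3LYP into B3LYP).  Both endpoints are reproduced exactly.
#' Points are 1-indexed in reports.
#'
#' @param start,end [RangeSepParams-class] endpoints.
#' @param nPoints number of points including the endpoints (>= 2).
#' @return a list of [RangeSepParams-class] with attribute `"table"`: a
#'   data.frame `point, t, alpha, beta, mu`.
#' @examples
#' pathTable(parameterPath(camB3LYP(), b3lyp(), 5))
#' @export
parameterPath <- function(start, end, nPoints = 5) {
  stopifnot(is(start, "RangeSepParams"), is(end, "RangeSepParams"))
  validObject(start); validObject(end)
  if (nPoints < 2) stop("nPoints must be >= 2")
  if (abs(start@mu - end@mu) > 0)
    warning("mu differs between endpoints; holding mu at the start value ",
            start@mu)
  t <- seq(0, 1, length.out = nPoints)
  alpha <- (1 - t) * start@alpha + t * end@alpha
  beta <- (1 - t) * start@beta + t * end@beta
  ## exact endpoints regardless of floating-point interpolation
  alpha[c(1, nPoints)] <- c(start@alpha, end@alpha)
  beta[c(1, nPoints)] <- c(start@beta, end@beta)
  path <- lapply(seq_len(nPoints), function(i)
    RangeSepParams(alpha[i], beta[i], start@mu))
  attr(path, "table") <- data.frame(point = seq_len(nPoints), t = t,
                                    alpha = alpha, beta = beta,
                                    mu = start@mu)
  path
}

#' @param path the list returned by [parameterPath()].
#' @rdname parameterPath
#' @export
pathTable <- function(path) attr(path, "table")

#' Write a parameter path as CSV
#'
#' Columns `point,t,alpha,beta,mu`; values round-trip through
#' [utils::read.csv()].
#'
#' @param path a [parameterPath()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
writePathCsv <- function(path, file) {
  tab <- pathTable(path)
  lines <- c("point,t,alpha,beta,mu",
             sprintf("%d,%.17g,%.17g,%.17g,%.17g", tab$point, tab$t,
                     tab$alpha, tab$beta, tab$mu))
  writeLines(lines, file)
  invisible(file)
}

#' Emit and decode a parameter-override stanza
#'
#' `emitOverrides()` renders a parameter set as a deterministic two-line
#' stanza: a human-readable comment followed by a single override line with
#' integer-scaled fields, using the ten-thousandths convention of
#' quantum-chemistry parameter overrides (each field is the value times
#' 10^4, zero-padded to five digits):
#'
#' ```
#' ! rangesep override alpha=0.1900 beta=0.4600 mu=0.3300 (fields = value x 1e4)
#' RangeSep(Alpha=01900,Beta=04600,Mu=03300)
#' ```
#'
#' The encoding resolution is 1e-4; parameters are validated to lie on that
#' grid so that `decodeOverrides(emitOverrides(p))` reproduces `p` exactly.
#' Translating the fields into a specific electronic-structure code's
#' internal override keywords is left to the user.
#'
#' @param p a [RangeSepParams-class] with alpha, beta, mu multiples of 1e-4.
#' @return character vector of stanza lines.
#' @export
emitOverrides <- function(p) {
  stopifnot(is(p, "RangeSepParams"))
  validObject(p)
  enc <- function(v, what) {
    u <- round(v * 1e4)
    if (abs(v * 1e4 - u) > 1e-6)
      stop(what, " = ", v, " is not representable at the 1e-4 encoding ",
           "resolution")
    sprintf("%05d", as.integer(u))
  }
  c(sprintf(
      "! rangesep override alpha=%.4f beta=%.4f mu=%.4f (fields = value x 1e4)",
      p@alpha, p@beta, p@mu),
    sprintf("RangeSep(Alpha=%s,Beta=%s,Mu=%s)",
            enc(p@alpha, "alpha"), enc(p@beta, "beta"), enc(p@mu, "mu")))
}

#' @param stanza character vector as produced by [emitOverrides()].
#' @rdname emitOverrides
#' @export
decodeOverrides <- function(stanza) {
  ln <- grep("^RangeSep\\(", stanza, value = TRUE)
  if (length(ln) != 1)
    stop("stanza must contain exactly one RangeSep(...) line")
  m <- regexec("^RangeSep\\(Alpha=(-?\\d+),Beta=(-?\\d+),Mu=(-?\\d+)\\)$", ln)
  g <- regmatches(ln, m)[[1]]
  if (length(g) != 4) stop("malformed RangeSep override line: ", ln)
  RangeSepParams(as.integer(g[2]) / 1e4, as.integer(g[3]) / 1e4,
                 as.integer(g[4]) / 1e4)
}
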