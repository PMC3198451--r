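#' Spearman-Brown prophecy correction of a half-test correlation
#'
#' `r_full = 2 r / (1 + r)`: the predicted full-length reliability when a
#' correlation was computed from test halves. Monotone increasing on
#' (-1, 1], fixing 0 and 1.
#'
#' @param r half-test correlation(s) in (-1, 1].
#' @return corrected correlation(s).
#' @examples
#' spearmanBrown(0.5)  # 0.6667
#' @export
spearmanBrown <- function(r) {
  stopifnot(all(r > -1), all(r <= 1))
  2 * r / (1 + r)
}

#' Split-half reliability of a component across subjects
#'
#' Correlates the odd- and even-half amplitude measures (one pair per
#' subject, see [splitHalfMeasures()]) over subjects and applies the
#' Spearman-Brown correction. Subjects with missing halves (too few
#' trials) are excluded with a warning, not imputed.
#'
#' @param halves data.frame with columns `subject`, `odd`, `even`
#'   (amplitudes in microvolts), or a named list of `c(odd=, even=)`
#'   pairs / `NULL`s keyed by subject.
#' @param component,channel metadata carried into the result.
#' @return one-row data.frame: `component`, `channel`, `r_half`, `r_sb`,
#'   `n_subjects`, `n_excluded`.
#' @export
splitHalfReliability <- function(halves, component = NA_character_,
                                 channel = "FCz") {
  if (is.list(halves) && !is.data.frame(halves)) {
    keep <- !vapply(halves, is.null, logical(1))
    nExcluded <- sum(!keep)
    if (nExcluded > 0L)
      warning(nExcluded, " subject(s) excluded: too few trials in a half")
    halves <- data.frame(
      subject = names(halves)[keep],
      odd = vapply(halves[keep], `[[`, numeric(1), "odd"),
      even = vapply(halves[keep], `[[`, numeric(1), "even"))
  } else nExcluded <- 0L
  stopifnot(all(c("odd", "even") %in% names(halves)))
  if (nrow(halves) < 3L)
    stop("need at least 3 subjects with both halves")
  r <- cor(halves$odd, halves$even)
  data.frame(component = component, channel = channel, r_half = r,
             r_sb = spearmanBrown(r), n_subjects = nrow(halves),
             n_excluded = nExcluded, stringsAsFactors = FALSE)
}

#' z-normalize a vector of per-subject measures
#'
#' Mean 0, SD 1 (denominator n - 1). Affine transformations of the input
#' leave the output unchanged (up to sign of the scale).
#'
#' @param x numeric vector, length >= 2, non-zero variance.
#' @return z-scores.
#' @export
zNormalize <- function(x) {
  stopifnot(length(x) >= 2)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-normalize")
  (x - mean(x)) / s
}

#' Bivariate regression between two component measures
#'
#' Ordinary least squares of `y` on `x`. With `standardize = TRUE`
#' (default) both variables are z-normalized first, so the slope equals
#' the Pearson correlation and `beta^2 = R^2`.
#'
#' @param x,y numeric vectors of per-subject measures (equal length >= 3).
#' @param standardize z-normalize both variables before fitting.
#' @return one-row data.frame: `beta` (slope), `sem` (its standard
#'   error), `t`, `p`, `r2`, `n`.
#' @export
bivariateRegression <- function(x, y, standardize = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values in regression inputs")
  if (standardize) {
    x <- zNormalize(x)
    y <- zNormalize(y)
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  co <- s$coefficients["x", ]
  data.frame(beta = unname(co["Estimate"]), sem = unname(co["Std. Error"]),
             t = unname(co["t value"]), p = unname(co["Pr(>|t|)"]),
             r2 = s$r.squared, n = length(x))
}
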