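#' Heterozygosity-based inbreeding measure
#'
#' Converts a nest's expected heterozygosity into an inbreeding measure
#' relative to the most heterozygous nest in the metapopulation, which is
#' taken to be non-inbred:
#' \deqn{F_h = (H_0 - H) / H_0 \in [0, 1].}
#'
#' @param h_snp Heterozygosity value(s), each in `[0, h_snp_0]`.
#' @param h_snp_0 Reference heterozygosity: the highest observed expected
#'   heterozygosity among all nests; must be positive.
#' @return Numeric vector of \eqn{F_h} values.
#' @export
#' @examples
#' fh(0.22, 0.44)  # 0.5
fh <- function(h_snp, h_snp_0) {
  if (!is.numeric(h_snp_0) || length(h_snp_0) != 1L ||
      h_snp_0 <= 0 || h_snp_0 > 1)
    stop("h_snp_0 must be a single value in (0, 1]", call. = FALSE)
  if (any(h_snp < 0, na.rm = TRUE))
    stop("h_snp must be >= 0", call. = FALSE)
  if (any(h_snp > h_snp_0 + 1e-12, na.rm = TRUE))
    stop("h_snp exceeds h_snp_0: the reference must be the maximum ",
         "observed heterozygosity", call. = FALSE)
  pmin(pmax((h_snp_0 - h_snp) / h_snp_0, 0), 1)
}

#' Overwinter survival under inbreeding load
#'
#' The assumed probability that a nest survives overwinter,
#' \deqn{S = s_0 e^{-B F},}
#' where \eqn{B} is the number of haploid lethal equivalents, \eqn{F} the
#' nest's inbreeding coefficient, and \eqn{s_0} the survival of a
#' non-inbred nest.
#'
#' @param f Inbreeding measure(s) in `[0, 1]`.
#' @param b Haploid lethal equivalents, `>= 0`.
#' @param s0 Baseline survival in `(0, 1]` (default 0.7).
#' @return Survival probabilities, clipped to `[0, 1]`.
#' @export
#' @examples
#' survival_under_load(0.5, b = 1, s0 = 0.7)  # 0.4246
survival_under_load <- function(f, b, s0 = 0.7) {
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("f must be within [0, 1]", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || b < 0)
    stop("b must be a single value >= 0", call. = FALSE)
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0 || s0 > 1)
    stop("s0 must be in (0, 1]", call. = FALSE)
  pmin(pmax(s0 * exp(-b * f), 0), 1)
}

#' Estimate haploid lethal equivalents from nest survival
#'
#' Estimates the inbreeding load \eqn{B} from binary overwinter nest
#' outcomes and inbreeding measures via
#' \deqn{B = -\log(S_{F_{max}} / S_{F_0}) / F_{max},}
#' where \eqn{S_{F_0}} and \eqn{S_{F_{max}}} are survival probabilities at
#' the lowest and highest observed inbreeding. With the default
#' `"fitted_logistic"` method both probabilities are predictions from a
#' logistic regression of survival on \eqn{F_h} (evaluated at
#' \eqn{F_h = 0} and \eqn{F_h = F_{max}}), which uses every nest and
#' avoids the degenerate 0/1 survival "probabilities" single extreme
#' nests would give. The `"raw_extremes"` method instead uses the
#' empirical survival of the nests at the minimum and maximum observed
#' \eqn{F_h} (and also accepts exact probabilities as `nest_survival`).
#'
#' @param nest_survival Binary outcomes (1 = survived), or survival
#'   probabilities for the `"raw_extremes"` method.
#' @param fh_values Inbreeding measures \eqn{F_h}, same length.
#' @param method `"fitted_logistic"` (default) or `"raw_extremes"`.
#' @param s0 Unused for estimation; retained in the output for context.
#' @return An object of class `load_estimate`: list with `b_hat`,
#'   `fh_max`, `s_at_f0`, `s_at_fmax`, `method`, `n`.
#' @export
#' @examples
#' f <- c(0, 0.5)
#' s <- c(0.7, 0.7 * exp(-1 * 0.5))
#' estimate_b(s, f, method = "raw_extremes")$b_hat  # exactly 1
estimate_b <- function(nest_survival, fh_values,
                       method = c("fitted_logistic", "raw_extremes"),
                       s0 = NULL) {
  method <- match.arg(method)
  if (length(nest_survival) != length(fh_values))
    stop("nest_survival and fh_values must have equal length", call. = FALSE)
  ok <- !is.na(nest_survival) & !is.na(fh_values)
  y <- as.numeric(nest_survival[ok])
  f <- as.numeric(fh_values[ok])
  if (length(unique(f)) < 2)
    stop("need at least 2 distinct Fh values", call. = FALSE)
  fmax <- max(f)
  if (fmax <= 0)
    stop("fh_max is 0: no inbreeding variation to estimate a load from",
         call. = FALSE)
  if (method == "fitted_logistic") {
    fit <- fit_logistic(cbind(`(Intercept)` = 1, fh = f), y)
    s_f0 <- stats::plogis(fit$coefficients[1])
    s_fmax <- stats::plogis(fit$coefficients[1] + fit$coefficients[2] * fmax)
  } else {
    s_f0 <- mean(y[f == min(f)])
    s_fmax <- mean(y[f == fmax])
    if (s_f0 <= 0 || s_fmax <= 0)
      stop("empirical survival of 0 at an Fh extreme: the raw_extremes ",
           "method is undefined; use method = \"fitted_logistic\"",
           call. = FALSE)
  }
  b_hat <- -log(s_fmax / s_f0) / fmax
  structure(list(b_hat = unname(b_hat), fh_max = fmax,
                 s_at_f0 = unname(s_f0), s_at_fmax = unname(s_fmax),
                 method = method, n = length(y)),
            class = "load_estimate")
}

#' @export
print.load_estimate <- function(x, ...) {
  cat(sprintf(
    "Inbreeding load (%s): B = %.3f haploid lethal equivalents\n  S(Fh=0) = %.3f, S(Fh=%.3f) = %.3f, n = %d nests\n",
    x$method, x$b_hat, x$s_at_f0, x$fh_max, x$s_at_fmax, x$n))
  invisible(x)
}
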