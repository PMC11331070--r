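#' Power-analysis scenario
#'
#' Describes one Monte-Carlo power-analysis scenario: the assumed true
#' model (inbreeding-load survival for nest mortality, a logistic
#' extinction model in heterozygosity for patch extinction), the
#' significance threshold, and the number of replicates.
#'
#' @param kind `"nest_mortality"` or `"extinction"`.
#' @param b Haploid lethal equivalents; may be a vector (default
#'   `c(1, 2.5, 5)`) — one power estimate per value. Used only for
#'   `kind = "nest_mortality"`.
#' @param s0 Baseline overwinter survival (default 0.7).
#' @param ext_intercept,ext_slope Assumed extinction log-odds model
#'   \eqn{L = 1.58 - 6.14 H}, chosen so extinction probability is 0.6 at
#'   the lowest and 0.25 at the highest observed heterozygosity. Used for
#'   `kind = "extinction"`.
#' @param alpha Significance threshold (default 0.05).
#' @param n_reps Monte-Carlo replicates per stratum (default 5000).
#' @param stratum Which strata to evaluate: `"both"` (default; every year
#'   plus all years pooled), `"per-year"`, or `"all"` (pooled only).
#' @param seed Scenario seed; per-stratum substreams are derived from it
#'   so per-year and pooled runs are independently reproducible.
#' @return An object of class `power_scenario`.
#' @export
power_scenario <- function(kind = c("nest_mortality", "extinction"),
                           b = c(1, 2.5, 5), s0 = 0.7,
                           ext_intercept = 1.58, ext_slope = -6.14,
                           alpha = 0.05, n_reps = 5000, seed = 1L,
                           stratum = c("both", "per-year", "all")) {
  kind <- match.arg(kind)
  stratum <- match.arg(stratum)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (any(b < 0)) stop("b must be >= 0", call. = FALSE)
  if (s0 <= 0 || s0 > 1) stop("s0 must be in (0, 1]", call. = FALSE)
  structure(list(kind = kind, b = b, s0 = s0,
                 ext_intercept = ext_intercept, ext_slope = ext_slope,
                 alpha = alpha, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), stratum = stratum),
            class = "power_scenario")
}

#' Build a power scenario from a generator configuration
#'
#' The generator configuration houses the assumed survival and extinction
#' model constants (`s0`, `b_true`, `ext_intercept`, `ext_slope_h`); this
#' helper turns them into the matching [power_scenario()].
#'
#' @param config A [generator_config()].
#' @param kind,... Passed to [power_scenario()].
#' @return A `power_scenario`.
#' @export
power_scenario_from_config <- function(config, kind = "nest_mortality", ...) {
  power_scenario(kind = kind, s0 = config$s0,
                 ext_intercept = config$ext_intercept,
                 ext_slope = config$ext_slope_h, ...)
}

# Strata (years with >= min_n units, plus "all"); warns about omissions.
.power_strata <- function(het, which = "both", min_n = 10) {
  yearly <- list()
  if (which %in% c("both", "per-year")) {
    counts <- table(het$year)
    keep <- names(counts)[counts >= min_n]
    dropped <- setdiff(names(counts), keep)
    if (length(dropped))
      warning("omitting strata with fewer than ", min_n, " units: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    yearly <- as.list(keep)
  }
  c(yearly, if (which %in% c("both", "all")) list("all"))
}

# Core Monte-Carlo loop: fixed heterozygosity values, resampled binary
# outcomes, logistic regression of outcome on heterozygosity, count of
# replicates with a converged fit and Wald p <= alpha.
.power_loop <- function(he, p_event, alpha, n_reps, seed) {
  set.seed(seed)
  x <- cbind(`(Intercept)` = 1, he = he)
  n_sig <- 0L
  n_nonconv <- 0L
  for (r in seq_len(n_reps)) {
    y <- stats::rbinom(length(he), 1L, p_event)
    fit <- tryCatch(fit_logistic(x, y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_nonconv <- n_nonconv + 1L        # counted as non-significant
    } else if (fit$p["he"] <= alpha) {
      n_sig <- n_sig + 1L
    }
  }
  list(power = n_sig / n_reps, n_nonconverged = n_nonconv)
}

#' Power to detect heterozygosity effects on overwinter nest mortality
#'
#' For each inbreeding-load value `b` in the scenario and each stratum
#' (each year with at least 10 nests, plus all years combined):
#' every nest's heterozygosity is converted to \eqn{F_h} relative to the
#' most heterozygous nest in the whole metapopulation, survival is drawn
#' as Bernoulli\eqn{(s_0 e^{-B F_h})}, and survival is regressed on
#' heterozygosity by logistic regression. Power is the proportion of
#' replicates in which the heterozygosity term is significant at
#' `alpha` (non-converged or separated fits count as non-significant).
#' Heterozygosity values are held fixed across replicates; only outcomes
#' are resampled.
#'
#' @param nest_het Nest-level heterozygosity estimates
#'   (from [heterozygosity()]): columns `unit_id`, `year`, `he`.
#' @param scenario A [power_scenario()] with `kind = "nest_mortality"`.
#' @return A `data.frame` with one row per (b, stratum): `kind`, `b`,
#'   `stratum`, `power`, `n_reps`, `n_units`, `n_nonconverged`.
#' @export
power_nest_mortality <- function(nest_het, scenario) {
  if (scenario$kind != "nest_mortality")
    stop("scenario kind must be nest_mortality", call. = FALSE)
  het <- nest_het[!is.na(nest_het$he), , drop = FALSE]
  h0 <- max(het$he)
  strata <- .power_strata(het, scenario$stratum)
  out <- list()
  for (bi in seq_along(scenario$b)) {
    b <- scenario$b[bi]
    for (si in seq_along(strata)) {
      s <- strata[[si]]
      sub <- if (identical(s, "all")) het else het[het$year == s, , drop = FALSE]
      f <- fh(sub$he, h0)
      p_surv <- survival_under_load(f, b = b, s0 = scenario$s0)
      res <- .power_loop(sub$he, p_surv, scenario$alpha, scenario$n_reps,
                         seed = scenario$seed + 997L * bi + si)
      out[[length(out) + 1L]] <- data.frame(
        kind = "nest_mortality", b = b, stratum = as.character(s),
        power = res$power, n_reps = scenario$n_reps,
        n_units = nrow(sub), n_nonconverged = res$n_nonconverged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Power to detect heterozygosity effects on population extinction
#'
#' For each stratum (years with at least 10 populations, plus pooled):
#' the true extinction probability of each population is
#' \eqn{P(\mathrm{Ext}) = \mathrm{logit}^{-1}(L)} with
#' \eqn{L = \mathrm{intercept} + \mathrm{slope} \cdot H} (optionally plus
#' demographic terms), extinctions are drawn by binomial sampling, and
#' extinction is regressed on heterozygosity. Power is the proportion of
#' significant replicates, as in [power_nest_mortality()].
#'
#' @param pop_het Population-level heterozygosity estimates: columns
#'   `unit_id`, `year`, `he`.
#' @param scenario A [power_scenario()] with `kind = "extinction"`.
#' @param demo_covariates Optional data.frame of demographic covariates
#'   (e.g. `log_nest_count`, `log_area`, `log_connectivity`), row-aligned
#'   with `pop_het`, whose effect on the true extinction log-odds is
#'   given by `demo_slopes` — allowing extinction scenarios where
#'   demography also acts.
#' @param demo_slopes Named coefficients for `demo_covariates` (e.g. from
#'   a [generator_config()]'s `demo_slopes`); covariates are centred
#'   before use so the intercept keeps its meaning.
#' @return A `data.frame`, one row per stratum, as in
#'   [power_nest_mortality()] (with `b = NA`).
#' @export
power_extinction <- function(pop_het, scenario, demo_covariates = NULL,
                             demo_slopes = NULL) {
  if (scenario$kind != "extinction")
    stop("scenario kind must be extinction", call. = FALSE)
  het <- pop_het
  lp_demo <- 0
  if (!is.null(demo_covariates)) {
    if (is.null(demo_slopes))
      stop("demo_slopes required with demo_covariates", call. = FALSE)
    use <- intersect(names(demo_slopes), names(demo_covariates))
    m <- scale(as.matrix(demo_covariates[, use, drop = FALSE]),
               center = TRUE, scale = FALSE)
    lp_demo <- drop(m %*% demo_slopes[use])
  }
  keep <- !is.na(het$he)
  het <- het[keep, , drop = FALSE]
  if (length(lp_demo) > 1) lp_demo <- lp_demo[keep]
  strata <- .power_strata(het, scenario$stratum)
  out <- list()
  for (si in seq_along(strata)) {
    s <- strata[[si]]
    sel <- if (identical(s, "all")) rep(TRUE, nrow(het)) else het$year == s
    sub <- het[sel, , drop = FALSE]
    lp <- scenario$ext_intercept + scenario$ext_slope * sub$he +
      (if (length(lp_demo) > 1) lp_demo[sel] else lp_demo)
    p_ext <- stats::plogis(lp)
    res <- .power_loop(sub$he, p_ext, scenario$alpha, scenario$n_reps,
                       seed = scenario$seed + 7919L + si)
    out[[length(out) + 1L]] <- data.frame(
      kind = "extinction", b = NA_real_, stratum = as.character(s),
      power = res$power, n_reps = scenario$n_reps,
      n_units = nrow(sub), n_nonconverged = res$n_nonconverged,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Tabulate power results
#'
#' Reshapes power results into a year-by-scenario table (one row per year
#' stratum plus `"all"`, one column per scenario), optionally writing it
#' as CSV.
#'
#' @param results Row-bound results from [power_nest_mortality()] and/or
#'   [power_extinction()].
#' @param file Optional CSV path.
#' @return The wide `data.frame` (invisibly if `file` is given).
#' @export
power_report <- function(results, file = NULL) {
  if (!nrow(results)) stop("no power results to report", call. = FALSE)
  label <- ifelse(results$kind == "extinction", "extinction",
                  paste0("nest_mortality_b", results$b))
  strata <- unique(results$stratum)
  years <- setdiff(strata, "all")
  years <- if (!anyNA(suppressWarnings(as.numeric(years))))
    years[order(as.numeric(years))] else sort(years)
  strata <- c(years, intersect("all", strata))
  wide <- data.frame(stratum = strata, stringsAsFactors = FALSE)
  for (l in unique(label)) {
    sub <- results[label == l, , drop = FALSE]
    wide[[l]] <- sub$power[match(strata, sub$stratum)]
  }
  if (!is.null(file)) {
    utils::write.csv(wide, file, row.names = FALSE)
    return(invisible(wide))
  }
  wide
}
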