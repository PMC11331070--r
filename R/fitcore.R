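#' Specification of the six extinction/mortality model structures
#'
#' Returns the fixed-effect term structure of one of the six model
#' designs used for every response:
#' \describe{
#'   \item{1}{heterozygosity only — no environmental or demographic
#'     variables;}
#'   \item{2}{heterozygosity plus all demographic and environmental
#'     covariates, no interactions;}
#'   \item{3}{model 2 plus interactions of heterozygosity with log nest
#'     count and log connectivity;}
#'   \item{4}{covariates plus year as a categorical variable and a
#'     separate heterozygosity slope per year (no continuous year term);}
#'   \item{5}{covariates plus the 1-generation population-trend category
#'     and a heterozygosity slope per trend category;}
#'   \item{6}{as model 5 with the 2-generation trend.}
#' }
#' In models 4-6 heterozygosity enters only through the interaction, so
#' each coefficient is the heterozygosity slope within that year or trend
#' stratum.
#'
#' @param model_id Integer 1-6.
#' @param response Response name (recorded in the spec).
#' @return An object of class `model_spec`: list with `model_id`,
#'   `response`, `terms` (right-hand-side terms for [fit_model()]).
#' @export
build_model_spec <- function(model_id, response = "annual_ext") {
  if (!is.numeric(model_id) || length(model_id) != 1L || !model_id %in% 1:6)
    stop("unknown model_id: must be 1..6", call. = FALSE)
  covs <- c("z_log_nest_count", "z_ntrend", "z_log_area",
            "z_log_connectivity", "z_host_abundance", "z_prop_low_veg",
            "z_prop_dry", "z_prop_grazed")
  terms <- switch(model_id,
    "z_he",
    c("z_he", covs),
    c("z_he", covs, "z_he:z_log_nest_count", "z_he:z_log_connectivity"),
    c(covs, "year_f", "z_he:year_f"),
    c(covs, "trend_1gen", "z_he:trend_1gen"),
    c(covs, "trend_2gen", "z_he:trend_2gen"))
  structure(list(model_id = as.integer(model_id), response = response,
                 terms = terms),
            class = "model_spec")
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits a binomial logit model to a binary response by iteratively
#' reweighted least squares, with step-halving so the deviance never
#' increases. Self-contained so that the Monte-Carlo power loop is fast
#' and has no model-fitting dependencies.
#'
#' Convergence is declared when the deviance changes by less than `tol`
#' between iterations. Under perfect separation (or any other failure to
#' converge) the fit is returned with `converged = FALSE` and the
#' coefficients of the last iterate; callers decide how to treat such
#' fits ([power_nest_mortality()] counts them as non-significant).
#'
#' @param x Design matrix (including an intercept column if wanted).
#' @param y Response vector; binary 0/1, or probabilities in `[0, 1]` for
#'   expected-value fits.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol Convergence tolerance on the deviance change (default 1e-8).
#' @return An object of class `logit_fit`: list with `terms`,
#'   `coefficients`, `se`, `z`, `p`, `converged`, `n`, `deviance`,
#'   `iterations`, and the per-iteration `deviance_trace`.
#' @export
#' @examples
#' x <- cbind(1, c(rep(1, 100), rep(0, 100)))
#' y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' fit_logistic(x, y)$coefficients[2]  # log odds ratio = log(30*90/(70*10))
fit_logistic <- function(x, y, max_iter = 50, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("x and y dimensions differ", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("response must be within [0, 1]", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1)))[seq_len(ncol(x))]
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  if (sum(const) > 1 || (any(const) && any(abs(x[1, const]) < .Machine$double.eps)))
    stop("design matrix has a constant non-intercept column", call. = FALSE)

  dev_of <- function(mu) {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  beta <- rep(0, ncol(x))
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  dev <- dev_of(mu)
  trace <- dev
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(x, z, w)
    if (fit$rank < ncol(x))
      stop("design matrix is rank deficient", call. = FALSE)
    beta_new <- fit$coefficients
    # step-halving guarantees the deviance is non-increasing
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      mu_try <- stats::plogis(drop(x %*% beta_try))
      dev_try <- dev_of(mu_try)
      if (dev_try <= dev + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta_try
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    delta <- dev - dev_try
    dev <- dev_try
    trace <- c(trace, dev)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (max(abs(eta)) > 20) converged <- FALSE   # separation: diverging logits

  w <- pmax(mu * (1 - mu), 1e-10)
  xtwx <- crossprod(x * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  se <- sqrt(diag(cov))
  zstat <- beta / se
  structure(list(terms = colnames(x),
                 coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 z = stats::setNames(zstat, colnames(x)),
                 p = stats::setNames(2 * stats::pnorm(-abs(zstat)), colnames(x)),
                 converged = converged,
                 n = n,
                 deviance = dev,
                 iterations = iter,
                 deviance_trace = trace),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Binomial logit fit (IRLS): n =", x$n,
      "deviance =", format(x$deviance, digits = 6),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Fit a model structure to an analysis table
#'
#' Builds the design matrix for a [build_model_spec()] structure from a
#' [build_analysis_table()] result and fits it with [fit_logistic()].
#' Year enters model 4 as a factor (`year_f`); trend categories enter
#' models 5-6 as factors.
#'
#' @param table Analysis table with response column `y`.
#' @param spec A `model_spec`, or a model id 1-6.
#' @param ... Passed to [fit_logistic()].
#' @return A `logit_fit` (with the spec attached as attribute `spec`).
#' @export
fit_model <- function(table, spec, ...) {
  if (!inherits(spec, "model_spec"))
    spec <- build_model_spec(spec, attr(table, "response") %||% "annual_ext")
  tab <- table
  if (any(grepl("year_f", spec$terms))) tab$year_f <- factor(tab$year)
  if (any(grepl("trend_1gen", spec$terms)))
    tab$trend_1gen <- factor(tab$trend_1gen,
                             levels = c("declined", "increased", "stable"))
  if (any(grepl("trend_2gen", spec$terms)))
    tab$trend_2gen <- factor(tab$trend_2gen,
                             levels = c("declined", "increased", "stable"))
  form <- stats::reformulate(spec$terms, response = "y")
  mf <- stats::model.frame(form, data = tab, na.action = stats::na.omit)
  x <- stats::model.matrix(stats::delete.response(stats::terms(form)), mf)
  y <- stats::model.response(mf)
  fit <- fit_logistic(x, y, ...)
  attr(fit, "spec") <- spec
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided Wald p-value for a fitted term
#'
#' @param fit A `logit_fit`.
#' @param term Term name (as in `fit$terms`).
#' @return The two-sided normal p-value.
#' @export
wald_pvalue <- function(fit, term) {
  if (!term %in% fit$terms)
    stop("term not in fit: ", term, call. = FALSE)
  unname(fit$p[term])
}
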