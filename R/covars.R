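#' Incidence-function-model patch connectivity
#'
#' Computes, for every patch, the connectivity
#' \deqn{S_i = \sum_{j \ne i} e^{-\alpha d_{ij}} N_{j,t-1},}
#' where \eqn{d_{ij}} is the Euclidean distance (km) between patches
#' \eqn{i} and \eqn{j} and \eqn{N_{j,t-1}} is the fall nest count of
#' source patch \eqn{j} in the previous year. Every patch occupied in the
#' previous year acts as a source, whether or not it was genotyped.
#'
#' @param patches Patch table with `patch_id`, `x_km`, `y_km`.
#' @param survey Survey table with fall counts (`patch_id`, `year`,
#'   `season`, `nest_count`).
#' @param year Focal year `t`; sources are the fall counts of `t - 1`.
#' @param alpha Dispersal-kernel rate per km; 1/alpha is the mean
#'   dispersal distance. Default 1.
#' @return A `data.frame` with `patch_id`, `year`, `s_i`.
#' @export
#' @examples
#' p <- data.frame(patch_id = c("a", "b"), x_km = c(0, 1), y_km = 0)
#' s <- data.frame(patch_id = "b", year = 0, season = "fall", nest_count = 10)
#' connectivity(p, s, year = 1)  # a: 10 * exp(-1)
connectivity <- function(patches, survey, year, alpha = 1) {
  prev <- survey[survey$season == "fall" & survey$year == year - 1, ,
                 drop = FALSE]
  if (!nrow(prev))
    stop("no fall survey available for year ", year - 1,
         " (connectivity in year ", year, " needs the prior fall counts)",
         call. = FALSE)
  n_prev <- prev$nest_count[match(patches$patch_id, prev$patch_id)]
  n_prev[is.na(n_prev)] <- 0
  xy <- cbind(patches$x_km, patches$y_km)
  d <- as.matrix(stats::dist(xy))
  w <- exp(-alpha * d)
  diag(w) <- 0
  data.frame(patch_id = patches$patch_id,
             year = year,
             s_i = as.vector(w %*% n_prev),
             stringsAsFactors = FALSE)
}

#' Neighbourhood growth-rate trend
#'
#' \eqn{Ntrend_i = S_{i,t} - S_{i,t-1}}: the year-over-year change in a
#' patch's connectivity, an indicator of metapopulation growth in its
#' vicinity (in a declining metapopulation it tends to be negative for
#' every patch, and positive in a growing one).
#'
#' @param s_t,s_tm1 Connectivity tables from [connectivity()] for years
#'   `t` and `t - 1`.
#' @return A `data.frame` with `patch_id`, `year` (of `s_t`), `ntrend`
#'   (NA for patches missing from either year).
#' @export
ntrend <- function(s_t, s_tm1) {
  prev <- s_tm1$s_i[match(s_t$patch_id, s_tm1$patch_id)]
  data.frame(patch_id = s_t$patch_id,
             year = s_t$year,
             ntrend = s_t$s_i - prev,
             stringsAsFactors = FALSE)
}

#' Classify population trends over one or two generations
#'
#' Classifies each patch-year as `"declined"`, `"increased"`, or
#' `"stable"` from its fall nest counts. Over one generation: declined iff
#' \eqn{N_t < N_{t-1}}, increased iff \eqn{N_t > N_{t-1}}, stable iff
#' equal. Over two generations: declined (increased) only if the count
#' strictly decreased (increased) across both transitions; anything else —
#' unchanged, or fluctuating with no directionality — is stable. Patch
#' years unoccupied at any required earlier time, or lacking counts back
#' to `t - horizon`, are `NA`.
#'
#' @param survey Survey table (fall rows are used).
#' @param horizon 1 or 2 generations.
#' @return A `data.frame` with `patch_id`, `year`, `trend`.
#' @export
#' @examples
#' s <- data.frame(patch_id = "a", year = 1:3, season = "fall",
#'                 nest_count = c(3, 5, 4))
#' classify_trend(s, horizon = 2)  # year 3: stable (no directionality)
classify_trend <- function(survey, horizon = 1) {
  if (!horizon %in% c(1, 2)) stop("horizon must be 1 or 2", call. = FALSE)
  fall <- survey[survey$season == "fall", , drop = FALSE]
  wide <- stats::reshape(fall[, c("patch_id", "year", "nest_count")],
                         idvar = "patch_id", timevar = "year",
                         direction = "wide")
  years <- sort(unique(fall$year))
  out <- list()
  for (t in years) {
    need <- t - rev(seq_len(horizon))
    cols <- paste0("nest_count.", c(need, t))
    if (!all(cols %in% names(wide))) next
    m <- as.matrix(wide[, cols, drop = FALSE])
    occupied_back <- rowSums(m[, seq_len(horizon), drop = FALSE] > 0, na.rm = FALSE) == horizon
    trend <- rep(NA_character_, nrow(wide))
    if (horizon == 1) {
      d <- m[, 2] - m[, 1]
      trend[occupied_back & d < 0] <- "declined"
      trend[occupied_back & d > 0] <- "increased"
      trend[occupied_back & d == 0] <- "stable"
    } else {
      d1 <- m[, 2] - m[, 1]
      d2 <- m[, 3] - m[, 2]
      trend[occupied_back & d1 < 0 & d2 < 0] <- "declined"
      trend[occupied_back & d1 > 0 & d2 > 0] <- "increased"
      trend[occupied_back & !(d1 < 0 & d2 < 0) & !(d1 > 0 & d2 > 0)] <- "stable"
    }
    trend[is.na(m[, 1]) | is.na(m[, ncol(m)])] <- NA_character_
    out[[length(out) + 1L]] <- data.frame(patch_id = wide$patch_id,
                                          year = t, trend = trend,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Continuous covariates that are z-standardized for modelling.
.continuous_covars <- c("he", "log_nest_count", "ntrend", "log_area",
                        "log_connectivity", "host_abundance",
                        "prop_low_veg", "prop_dry", "prop_grazed")

#' Build the per-model analysis table
#'
#' Assembles the filtered, transformed, and z-standardized dataset for one
#' of the three responses and one of the six model structures (see
#' [build_model_spec()]). Filtering applies, in order:
#' \enumerate{
#'   \item genotype-derived unit availability (only units with a
#'     heterozygosity estimate — at least two genotyped individuals —
#'     enter);
#'   \item removal of patch-years with missing fall survey data (and, for
#'     the overwinter responses, missing spring data);
#'   \item for the nest-mortality response, removal of merged nests
#'     (`n_families > 1`);
#'   \item for models 5-6, availability of the 1- or 2-generation
#'     population trend category.
#' }
#' Responses: `annual_ext` is 1 for a patch occupied in fall of year `t`
#' and empty the following fall; `overwinter_ext` is 1 for a patch
#' occupied in fall with no surviving nest the following spring (a patch
#' can be overwinter-extinct yet not annually extinct — a rescue event);
#' `nest_mortality` is 1 for a nest present in fall that died by spring.
#'
#' Nest count, patch area, and connectivity enter as natural logs;
#' connectivity uses [connectivity()] with the supplied `alpha` and the
#' neighbourhood trend is their year-over-year difference. All continuous
#' covariates are z-standardized (columns prefixed `z_`) over the final
#' analysis subset, so standardized coefficients are comparable across
#' covariates within a model.
#'
#' @param patches,survey Tables from the generator (or read from disk).
#' @param het Heterozygosity estimates from [heterozygosity()]:
#'   population-level for the extinction responses, nest-level for
#'   `nest_mortality`.
#' @param nests Nest table; required for `nest_mortality`.
#' @param response One of `"annual_ext"`, `"overwinter_ext"`,
#'   `"nest_mortality"`.
#' @param model_id Model structure 1-6; controls which rows must have
#'   trend categories available.
#' @param alpha Dispersal-kernel rate for connectivity (default 1).
#' @param standardize If `TRUE` (default) add `z_*` columns computed on
#'   the final subset.
#' @return A `data.frame`, one row per patch-year (or nest), with the
#'   response in column `y`, raw covariates, trend categories, and
#'   standardized copies. Attributes `response` and `model_id` record the
#'   design.
#' @export
build_analysis_table <- function(patches, survey, het, nests = NULL,
                                 response = c("annual_ext", "overwinter_ext",
                                              "nest_mortality"),
                                 model_id = 2, alpha = 1,
                                 standardize = TRUE) {
  response <- match.arg(response)
  if (!model_id %in% 1:6) stop("model_id must be in 1..6", call. = FALSE)
  if (response == "nest_mortality" && is.null(nests))
    stop("nests table required for the nest_mortality response", call. = FALSE)

  fall <- survey[survey$season == "fall", , drop = FALSE]
  spring <- survey[survey$season == "spring", , drop = FALSE]
  years <- sort(unique(fall$year))
  # connectivity needs fall t-1; ntrend needs fall t-2
  usable_years <- years[years - 2 >= min(years)]
  if (response == "annual_ext")
    usable_years <- usable_years[usable_years + 1 <= max(years)]
  if (!length(usable_years))
    stop("not enough survey years to build covariates", call. = FALSE)

  conn <- lapply(c(usable_years[1] - 1, usable_years), function(t)
    connectivity(patches, survey, t, alpha = alpha))
  names(conn) <- as.character(c(usable_years[1] - 1, usable_years))

  tr1 <- classify_trend(survey, 1)
  tr2 <- classify_trend(survey, 2)

  rows <- list()
  for (t in usable_years) {
    f_t <- fall[fall$year == t, , drop = FALSE]
    occ <- f_t[f_t$nest_count > 0, , drop = FALSE]
    if (!nrow(occ)) next
    st <- conn[[as.character(t)]]
    stm1 <- conn[[as.character(t - 1)]]
    ntr <- ntrend(st, stm1)
    pi <- match(occ$patch_id, patches$patch_id)
    base <- data.frame(patch_id = occ$patch_id, year = t,
                       nest_count = occ$nest_count,
                       log_nest_count = log(occ$nest_count),
                       area = patches$area[pi],
                       log_area = log(patches$area[pi]),
                       s_i = st$s_i[match(occ$patch_id, st$patch_id)],
                       ntrend = ntr$ntrend[match(occ$patch_id, ntr$patch_id)],
                       host_abundance = patches$host_abundance[pi],
                       prop_low_veg = patches$prop_low_veg[pi],
                       prop_dry = patches$prop_dry[pi],
                       prop_grazed = patches$prop_grazed[pi],
                       trend_1gen = tr1$trend[match(paste(occ$patch_id, t),
                                                    paste(tr1$patch_id, tr1$year))],
                       trend_2gen = tr2$trend[match(paste(occ$patch_id, t),
                                                    paste(tr2$patch_id, tr2$year))],
                       stringsAsFactors = FALSE)

    if (response == "annual_ext") {
      nxt <- fall[fall$year == t + 1, , drop = FALSE]
      nc <- nxt$nest_count[match(occ$patch_id, nxt$patch_id)]
      base$y <- as.integer(!is.na(nc) & nc == 0)
      base <- base[!is.na(nc), , drop = FALSE]   # missing-survey removal
    } else if (response == "overwinter_ext") {
      sp <- spring[spring$year == t, , drop = FALSE]
      nc <- sp$nest_count[match(occ$patch_id, sp$patch_id)]
      base$y <- as.integer(!is.na(nc) & nc == 0)
      base <- base[!is.na(nc), , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- base
  }
  tab <- do.call(rbind, rows)

  if (response == "nest_mortality") {
    nst <- nests[nests$n_families == 1, , drop = FALSE]   # merged-nest removal
    nst <- nst[nst$year %in% usable_years, , drop = FALSE]
    key_t <- paste(tab$patch_id, tab$year)
    idx <- match(paste(nst$patch_id, nst$year), key_t)
    keep <- !is.na(idx)
    nst <- nst[keep, , drop = FALSE]
    tab <- tab[idx[keep], , drop = FALSE]
    tab$nest_id <- nst$nest_id
    tab$y <- as.integer(nst$survived_overwinter == 0)
    h <- het[het$level == "nest", , drop = FALSE]
    tab$he <- h$he[match(paste(nst$nest_id, nst$year),
                         paste(h$unit_id, h$year))]
  } else {
    h <- het[het$level == "population", , drop = FALSE]
    tab$he <- h$he[match(paste(tab$patch_id, tab$year),
                         paste(h$unit_id, h$year))]
  }
  tab <- tab[!is.na(tab$he), , drop = FALSE]   # >= 2 genotypes per unit

  if (model_id == 5) tab <- tab[!is.na(tab$trend_1gen), , drop = FALSE]
  if (model_id == 6) tab <- tab[!is.na(tab$trend_2gen), , drop = FALSE]

  if (model_id >= 2) {
    if (any(tab$s_i == 0))
      stop("connectivity is zero for patch(es) ",
           paste(unique(tab$patch_id[tab$s_i == 0]), collapse = ", "),
           ": log connectivity is undefined; exclude these patch-years ",
           "(this can only happen when no patch was occupied in the prior year)",
           call. = FALSE)
  }
  tab$log_connectivity <- ifelse(tab$s_i > 0, log(tab$s_i), NA_real_)

  if (standardize) {
    for (v in .continuous_covars) {
      x <- tab[[v]]
      s <- stats::sd(x, na.rm = TRUE)
      tab[[paste0("z_", v)]] <- if (is.na(s) || s == 0) x * 0 else
        (x - mean(x, na.rm = TRUE)) / s
    }
  }
  rownames(tab) <- NULL
  attr(tab, "response") <- response
  attr(tab, "model_id") <- model_id
  tab
}
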