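#' Configuration for the synthetic metapopulation generator
#'
#' Bundles every tunable parameter of the synthetic data generator. The
#' defaults reproduce the statistical structure of the study system the
#' package targets: roughly 20% of patches occupied in a given year, local
#' population sizes of 1 to ~94 larval nests with a median of 3, short
#' (median ~2 year) periods of continuous occupancy, an overwinter nest
#' survival process \eqn{S = S_0 e^{-B F}}, and three larvae genotyped at
#' 245 biallelic SNPs per nest.
#'
#' The logistic extinction constants (`ext_intercept`, `ext_slope_h`,
#' `demo_slopes`) are housed here because they define the assumed
#' patch-extinction model used by the power analysis
#' (see [power_scenario_from_config()]); patch extinction in the simulated
#' dynamics itself is emergent — a patch goes extinct overwinter when all
#' of its nests die.
#'
#' @param n_patches Number of habitat patches.
#' @param extent_km Width and height of the rectangular study extent, km.
#' @param n_years Number of recorded survey years (at least 3, so that
#'   two-generation population trends can be classified).
#' @param n_loci Number of biallelic SNP loci.
#' @param founder_maf_range Lower and upper bound of the regional
#'   minor-allele-frequency distribution, each in (0, 0.5].
#' @param target_occupancy Long-run fraction of patches occupied at the
#'   fall census; colonization intensity is calibrated to hold this at
#'   stationarity.
#' @param s0 Baseline overwinter nest survival probability (survival of a
#'   non-inbred nest).
#' @param b_true Haploid lethal equivalents used when simulating
#'   overwinter nest survival, \eqn{S = s_0 e^{-B F}}.
#' @param ext_intercept,ext_slope_h Log-odds intercept and slope on
#'   heterozygosity of the assumed patch-extinction model
#'   \eqn{L = 1.58 - 6.14 H} (defaults match the extinction probabilities
#'   0.6 and 0.25 at the low and high ends of observed heterozygosity).
#' @param demo_slopes Named numeric vector: assumed log-odds coefficients
#'   of `log_nest_count`, `log_area` and `log_connectivity` in extended
#'   extinction scenarios.
#' @param rescue_scale Multiplier on the recolonization (rescue) intensity
#'   acting between the spring and fall censuses. `0` disables rescue, so
#'   every overwinter extinction is also an annual extinction.
#' @param larvae_genotyped_per_nest Larvae genotyped per nest.
#' @param merged_nest_fraction Fraction of nests containing larvae from a
#'   second full-sib family (these trigger the merged-nest filter).
#' @param missing_call_rate Independent per-call missingness probability.
#' @param seed Integer RNG seed; identical configurations with identical
#'   seeds yield identical datasets.
#'
#' @return An object of class `generator_config` (a named list).
#' @seealso [generate_patches()], [simulate_dynamics()], [write_dataset()]
#' @export
#' @examples
#' cfg <- generator_config(n_patches = 50, n_years = 4, n_loci = 20, seed = 1)
#' str(cfg[c("n_patches", "target_occupancy", "s0", "b_true")])
generator_config <- function(n_patches = 400,
                             extent_km = c(50, 70),
                             n_years = 10,
                             n_loci = 245,
                             founder_maf_range = c(0.1, 0.5),
                             target_occupancy = 0.20,
                             s0 = 0.7,
                             b_true = 1,
                             ext_intercept = 1.58,
                             ext_slope_h = -6.14,
                             demo_slopes = c(log_nest_count = -0.6,
                                             log_area = -0.2,
                                             log_connectivity = -0.3),
                             rescue_scale = 1,
                             larvae_genotyped_per_nest = 3,
                             merged_nest_fraction = 0.05,
                             missing_call_rate = 0.03,
                             seed = 1L) {
  stop_cfg <- function(msg) stop("invalid generator configuration: ", msg,
                                 call. = FALSE)
  if (!is.numeric(n_patches) || length(n_patches) != 1L || n_patches < 2)
    stop_cfg("n_patches must be a single count >= 2")
  if (!is.numeric(extent_km) || length(extent_km) != 2L || any(extent_km <= 0))
    stop_cfg("extent_km must be two positive numbers (width, height)")
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years < 1)
    stop_cfg("n_years must be a single positive count")
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop_cfg("n_loci must be >= 1")
  if (!is.numeric(founder_maf_range) || length(founder_maf_range) != 2L ||
      founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
      founder_maf_range[1] > founder_maf_range[2])
    stop_cfg("founder_maf_range must be within (0, 0.5] and ordered")
  for (nm in c("target_occupancy", "s0", "rescue_scale",
               "merged_nest_fraction", "missing_call_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop_cfg(paste(nm, "must be a single non-negative number"))
  }
  if (target_occupancy <= 0 || target_occupancy > 1)
    stop_cfg("target_occupancy must be in (0, 1]")
  if (s0 <= 0 || s0 > 1) stop_cfg("s0 must be in (0, 1]")
  if (merged_nest_fraction > 1) stop_cfg("merged_nest_fraction must be <= 1")
  if (missing_call_rate > 1) stop_cfg("missing_call_rate must be <= 1")
  if (b_true < 0) stop_cfg("b_true must be >= 0")
  if (larvae_genotyped_per_nest < 1)
    stop_cfg("larvae_genotyped_per_nest must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || abs(seed) >= 2^31 - 2)
    stop_cfg("seed must be a single 32-bit integer")
  cfg <- list(n_patches = as.integer(n_patches),
              extent_km = as.numeric(extent_km),
              n_years = as.integer(n_years),
              n_loci = as.integer(n_loci),
              founder_maf_range = as.numeric(founder_maf_range),
              target_occupancy = target_occupancy,
              s0 = s0, b_true = b_true,
              ext_intercept = ext_intercept, ext_slope_h = ext_slope_h,
              demo_slopes = demo_slopes,
              rescue_scale = rescue_scale,
              larvae_genotyped_per_nest = as.integer(larvae_genotyped_per_nest),
              merged_nest_fraction = merged_nest_fraction,
              missing_call_rate = missing_call_rate,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# Internal generator constants, calibrated once against the study
# conditions the defaults encode (occupancy, size distribution, He-logN
# correlation) and then frozen. Not user-tunable.
.gen_const <- list(
  burn_in = 70,            # years of unrecorded dynamics before sampling
  cal_adapt = 50,          # burn-in years of adaptive calibration
  founder_genomes = 4,     # one mated female: 4 haploid genomes
  growth_mean = 2.1,       # mean per-nest summer multiplication rate
  growth_sd_year = 0.18,   # lognormal sd of the shared year effect
  colonist_extra = 0.7,    # colonist nests ~ 1 + Poisson(colonist_extra)
  nest_cap = 94L,          # ceiling on local population size (nests)
  cap_per_area = 18,       # carrying capacity (nests) per unit patch area
  drift_genomes_per_nest = 4, # effective genomes per nest for drift
  c_init = 0.05,           # starting colonization intensity
  s_background = 0.5       # background propagule pressure from patches
                           # outside the modelled network
)

#' Generate the habitat patch network
#'
#' Places `n_patches` patches uniformly at random inside the study extent
#' and draws static patch attributes: a right-skewed (lognormal) patch
#' area, an ordinal host-plant abundance score (1 = sparse host, 3 = host
#' abundant enough to support many larval groups), and habitat-quality
#' fractions (proportion of dry host plants, of host growing in low
#' vegetation, and of the patch that is grazed). Patches are assigned to
#' three regions by longitudinal band.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` with columns `patch_id`, `x_km`, `y_km`, `area`,
#'   `host_abundance`, `prop_dry`, `prop_low_veg`, `prop_grazed`, `region`.
#' @export
#' @examples
#' p <- generate_patches(generator_config(n_patches = 10, seed = 7))
#' head(p)
generate_patches <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config object", call. = FALSE)
  set.seed(config$seed)
  np <- config$n_patches
  x <- stats::runif(np, 0, config$extent_km[1])
  y <- stats::runif(np, 0, config$extent_km[2])
  area <- stats::rlnorm(np, meanlog = 0, sdlog = 0.9)
  host <- sample(1:3, np, replace = TRUE, prob = c(0.45, 0.40, 0.15))
  prop_dry <- stats::rbeta(np, 2, 5)
  prop_low_veg <- stats::rbeta(np, 4, 3)
  prop_grazed <- stats::rbeta(np, 1.5, 5)
  band <- cut(x, breaks = stats::quantile(x, c(0, 1 / 3, 2 / 3, 1)),
              labels = c("west", "central", "east"), include.lowest = TRUE)
  data.frame(patch_id = sprintf("P%04d", seq_len(np)),
             x_km = x, y_km = y, area = area,
             host_abundance = host,
             prop_dry = prop_dry, prop_low_veg = prop_low_veg,
             prop_grazed = prop_grazed,
             region = as.character(band),
             stringsAsFactors = FALSE)
}

# Draw diploid parent genotypes (alternate-allele counts 0/1/2) at allele
# frequencies p with a heterozygote deficit controlled by inbreeding
# coefficient f: P(het) = 2pq(1-f), homozygotes get the excess F*pq each.
# p and f are recycled to a common length.
.draw_parent_genotypes <- function(p, f) {
  n <- max(length(p), length(f))
  p <- rep_len(p, n)
  f <- rep_len(f, n)
  q <- 1 - p
  p2 <- p^2 + f * p * q        # P(genotype 2)
  p1 <- 2 * p * q * (1 - f)    # P(genotype 1)
  u <- stats::runif(n)
  ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
}

# Mendelian segregation: one offspring allele from each parent; a parent
# with genotype g transmits the alternate allele with probability g/2.
.mendelian_offspring <- function(g1, g2) {
  a1 <- stats::rbinom(length(g1), 1L, g1 / 2)
  a2 <- stats::rbinom(length(g2), 1L, g2 / 2)
  as.integer(a1 + a2)
}

#' Simulate metapopulation dynamics, nests, and genotypes
#'
#' Runs a stochastic patch-occupancy simulation with an inbreeding-load
#' overwinter survival process and records fall/spring surveys, per-nest
#' outcomes, and SNP genotypes of sampled larvae for `n_years` years
#' (after an unrecorded burn-in during which colonization intensity is
#' calibrated so occupancy settles at `target_occupancy`).
#'
#' The yearly cycle for a patch with fall nest count \eqn{N_t}:
#' \enumerate{
#'   \item Overwinter, each nest survives independently with probability
#'     \eqn{s_0 e^{-B F}} where \eqn{F} is the population inbreeding
#'     coefficient; the patch is extinct in spring if all nests die.
#'   \item Surviving populations multiply over summer (shared lognormal
#'     year effect, Poisson reproduction, capped by an area-dependent
#'     carrying capacity and the global ceiling of 94 nests); their allele
#'     frequencies drift through a finite parental pool and \eqn{F}
#'     increments by \eqn{1/(2 N_t)}.
#'   \item Patches empty at the fall census may be colonized (probability
#'     \eqn{1 - e^{-c S_i}} with \eqn{S_i} incidence-function
#'     connectivity); patches that went extinct overwinter may be rescued
#'     before the next fall census with probability
#'     \eqn{1 - e^{-\mathrm{rescue\_scale} \cdot c S_i}}. Founders carry
#'     four haploid genomes sampled from the regional allele pool and
#'     reset \eqn{F} to zero.
#' }
#'
#' Genotypes: each nest is a full-sib family; two parents are drawn from
#' the patch allele frequencies with heterozygote deficit \eqn{2pq(1-F)},
#' larvae by Mendelian segregation. A `merged_nest_fraction` of nests
#' receives one larva from a second family of the same patch. Calls are
#' masked independently at `missing_call_rate`.
#'
#' Spring survey rows carry the year of the preceding fall: fall of year
#' `t` is the September census, spring of year `t` the following March, so
#' within a `(patch_id, year)` pair the spring count never exceeds the
#' fall count.
#'
#' @param patches Patch table from [generate_patches()].
#' @param config The same [generator_config()] used for the patches.
#' @return A list with elements `survey` (patch x year x season nest
#'   counts), `nests` (per-nest family count, true inbreeding coefficient
#'   and overwinter survival), and `genotypes` (wide table, one row per
#'   genotyped larva with `locus_*` columns coded 0/1/2/NA).
#' @export
#' @examples
#' cfg <- generator_config(n_patches = 60, n_years = 4, n_loci = 30, seed = 2)
#' sim <- simulate_dynamics(generate_patches(cfg), cfg)
#' table(sim$survey$season)
simulate_dynamics <- function(patches, config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config object", call. = FALSE)
  if (config$n_years < 3)
    stop("invalid generator configuration: n_years must be >= 3 ",
         "(trend classification needs counts back to t - 2)", call. = FALSE)
  if (nrow(patches) != config$n_patches)
    stop("patches does not match config$n_patches", call. = FALSE)
  set.seed(config$seed + 1L)
  k <- .gen_const
  np <- config$n_patches
  L <- config$n_loci
  p0 <- stats::runif(L, config$founder_maf_range[1], config$founder_maf_range[2])
  D <- as.matrix(stats::dist(cbind(patches$x_km, patches$y_km)))
  Kmat <- exp(-D)            # dispersal kernel, alpha = 1 per km
  diag(Kmat) <- 0
  cap <- pmin(k$nest_cap, pmax(2L, as.integer(round(k$cap_per_area * patches$area))))

  founder_freqs <- function(females) {
    # each founding mated female contributes 4 haploid genomes sampled
    # from the regional allele pool
    n <- length(females)
    g <- k$founder_genomes * females
    matrix(stats::rbinom(n * L, rep(g, L), rep(p0, each = n)) / rep(g, L),
           nrow = n, ncol = L)
  }

  # state
  N <- integer(np)
  Fpop <- numeric(np)
  P <- matrix(0, np, L)
  occ0 <- stats::runif(np) < config$target_occupancy
  N[occ0] <- pmin(cap[occ0], 1L + stats::rpois(sum(occ0), 2))
  P[occ0, ] <- founder_freqs(rep(1L, sum(occ0)))

  c_col <- k$c_init
  c_avg <- 0
  n_avg <- 0L
  occ_bar <- config$target_occupancy
  total_years <- k$burn_in + config$n_years

  survey_rows <- vector("list", config$n_years * 2L)
  nest_rows <- vector("list", config$n_years)
  geno_rows <- vector("list", config$n_years)

  for (t in seq_len(total_years)) {
    recording <- t > k$burn_in
    yr <- t - k$burn_in
    occ <- N > 0L
    occ_bar <- if (t == 1) mean(occ) else 0.5 * occ_bar + 0.5 * mean(occ)
    # after calibration, colonization pressure is regulated by regional
    # density dependence: recolonization is relaxed when occupancy runs
    # below its long-run level and damped when above
    c_eff <- if (t <= k$cal_adapt) c_col else
      c_col * min(max((config$target_occupancy / max(mean(occ), 0.02))^3,
                      0.3), 3)
    S <- as.vector(Kmat %*% N)
    surv_p <- config$s0 * exp(-config$b_true * pmin(1, Fpop))

    if (recording) {
      # ---- record fall survey and per-nest outcomes -------------------
      survey_rows[[2L * yr - 1L]] <- data.frame(
        patch_id = patches$patch_id, year = yr, season = "fall",
        nest_count = N, stringsAsFactors = FALSE)

      occ_idx <- which(occ)
      n_nests_p <- N[occ_idx]
      nest_patch <- rep.int(occ_idx, n_nests_p)
      n_nests <- length(nest_patch)
      within <- sequence(n_nests_p)
      nest_id <- sprintf("%s_Y%02d_N%02d", patches$patch_id[nest_patch], yr, within)
      f_nest <- pmin(1, Fpop[nest_patch])
      survived <- stats::rbinom(n_nests, 1L, surv_p[nest_patch])
      merged <- stats::runif(n_nests) < config$merged_nest_fraction
      if (n_nests > 0) nest_rows[[yr]] <- data.frame(
        nest_id = nest_id, patch_id = patches$patch_id[nest_patch],
        year = yr, n_families = 1L + as.integer(merged),
        f_true = f_nest, survived_overwinter = survived,
        stringsAsFactors = FALSE)

      # ---- genotypes: one family per nest plus merged second families --
      fam_patch <- c(nest_patch, nest_patch[merged])
      fam_f <- c(f_nest, f_nest[merged])
      n_fam <- length(fam_patch)
      pmat <- P[fam_patch, , drop = FALSE]
      G1 <- matrix(.draw_parent_genotypes(as.vector(pmat), rep(fam_f, L)),
                   n_fam, L)
      G2 <- matrix(.draw_parent_genotypes(as.vector(pmat), rep(fam_f, L)),
                   n_fam, L)
      kl <- config$larvae_genotyped_per_nest
      # merged nests hand one larva slot to their second family
      n_second <- ifelse(merged, pmin(1L, kl - 1L), 0L)
      fam_of_larva <- c(rep.int(seq_len(n_nests), kl - n_second),
                        rep.int(n_nests + seq_len(sum(merged)),
                                n_second[merged]))
      larva_nest <- c(rep.int(seq_len(n_nests), kl - n_second),
                      rep.int(which(merged), n_second[merged]))
      M <- length(fam_of_larva)
      calls <- matrix(.mendelian_offspring(as.vector(G1[fam_of_larva, , drop = FALSE]),
                                           as.vector(G2[fam_of_larva, , drop = FALSE])),
                      M, L)
      if (config$missing_call_rate > 0)
        calls[stats::runif(M * L) < config$missing_call_rate] <- NA_integer_
      ord <- order(larva_nest)
      calls <- calls[ord, , drop = FALSE]
      larva_nest <- larva_nest[ord]
      within_l <- stats::ave(seq_along(larva_nest), larva_nest,
                             FUN = seq_along)
      gdf <- data.frame(
        individual_id = sprintf("%s_L%d", nest_id[larva_nest], within_l),
        nest_id = nest_id[larva_nest],
        patch_id = patches$patch_id[nest_patch[larva_nest]],
        year = yr, stringsAsFactors = FALSE)
      colnames(calls) <- sprintf("locus_%04d", seq_len(L))
      if (n_nests > 0) geno_rows[[yr]] <- cbind(gdf, as.data.frame(calls))

      spring <- integer(np)
      if (n_nests > 0)
        spring[occ_idx] <- as.integer(rowsum(survived, nest_patch)[, 1])
      survey_rows[[2L * yr]] <- data.frame(
        patch_id = patches$patch_id, year = yr, season = "spring",
        nest_count = spring, stringsAsFactors = FALSE)
    } else {
      spring <- stats::rbinom(np, N, surv_p)
    }

    overwinter_ext <- occ & spring == 0L

    # ---- summer: growth, drift, inbreeding accumulation ----------------
    lam_year <- exp(stats::rnorm(1, log(k$growth_mean), k$growth_sd_year))
    alive <- spring > 0L
    Nn <- integer(np)
    Nn[alive] <- pmin(cap[alive],
                      pmax(1L, stats::rpois(sum(alive), lam_year * spring[alive])))
    if (any(alive)) {
      g <- k$drift_genomes_per_nest * Nn[alive]
      P[alive, ] <- matrix(
        stats::rbinom(sum(alive) * L, rep(g, L), as.vector(P[alive, , drop = FALSE])) /
          rep(g, L),
        sum(alive), L)
      Fpop[alive] <- pmin(1, Fpop[alive] + 1 / (2 * N[alive]))
      # genetic rescue: an immigrant mated female joins the breeding pool
      # with probability increasing in connectivity, diluting inbreeding
      # and pulling allele frequencies toward the regional pool
      imm <- alive & stats::runif(np) < 1 - exp(-c_eff * S)
      if (any(imm)) {
        w <- 1 / (2 * Nn[imm] + 1)
        Fpop[imm] <- (1 - w) * Fpop[imm]
        P[imm, ] <- (1 - w) * P[imm, , drop = FALSE] +
          w * founder_freqs(rep(1L, sum(imm)))
      }
    }

    # ---- colonization of patches empty at the fall census --------------
    col_new <- which(!occ &
                       stats::runif(np) < 1 - exp(-c_eff * (S + k$s_background)))
    # ---- rescue of patches that went extinct overwinter ----------------
    resc <- which(overwinter_ext &
                    stats::runif(np) <
                      1 - exp(-config$rescue_scale * c_eff * (S + k$s_background)))
    founded <- c(col_new, resc)
    if (length(founded)) {
      # well-connected patches tend to be colonized by several mated
      # females, giving them larger initial populations and higher
      # founder diversity
      females <- 1L + stats::rpois(length(founded),
                                   pmin(2, c_eff * S[founded]))
      Nn[founded] <- pmin(cap[founded],
                          females +
                            stats::rpois(length(founded),
                                         k$colonist_extra * females))
      Fpop[founded] <- 0
      P[founded, ] <- founder_freqs(females)
    }

    # stochastic-approximation calibration of the base colonization
    # intensity toward the target occupancy: large decaying gain while
    # burning in, then a small persistent integral correction
    gain <- max(1.0 / sqrt(t), 0.35)
    c_col <- c_col * exp(gain * (config$target_occupancy - occ_bar) /
                           config$target_occupancy)
    N <- Nn
  }

  list(survey = do.call(rbind, survey_rows),
       nests = do.call(rbind, nest_rows),
       genotypes = do.call(rbind, geno_rows))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `patches.csv`, `survey.csv`, `nests.csv`, `genotypes.csv` and a
#' `provenance.yaml` recording the full generator configuration (including
#' the seed) to `out_dir`. The files round-trip losslessly through
#' [read_dataset()] and [read_genotypes()].
#'
#' @param sim List returned by [simulate_dynamics()].
#' @param patches Patch table from [generate_patches()].
#' @param config The [generator_config()] that produced the data.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths of the files written.
#' @export
write_dataset <- function(sim, patches, config, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, c("patches.csv", "survey.csv", "nests.csv",
                                "genotypes.csv", "provenance.yaml"))
  utils::write.csv(patches, paths[1], row.names = FALSE)
  utils::write.csv(sim$survey, paths[2], row.names = FALSE)
  utils::write.csv(sim$nests, paths[3], row.names = FALSE)
  utils::write.csv(sim$genotypes, paths[4], row.names = FALSE)
  prov <- unclass(config)
  prov$demo_slopes <- as.list(prov$demo_slopes)
  yaml::write_yaml(list(generator = "metahet", config = prov), paths[5])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV files.
#' @return A list with `patches`, `survey`, `nests`, `genotypes`, and
#'   `config` (the provenance record, a plain list).
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("patches.csv", "survey.csv", "nests.csv",
                           "genotypes.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing dataset files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  prov_path <- file.path(dir, "provenance.yaml")
  prov <- if (file.exists(prov_path)) yaml::read_yaml(prov_path) else NULL
  list(patches = utils::read.csv(need[1], stringsAsFactors = FALSE),
       survey = utils::read.csv(need[2], stringsAsFactors = FALSE),
       nests = utils::read.csv(need[3], stringsAsFactors = FALSE),
       genotypes = read_genotypes(need[4]),
       config = prov$config)
}
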