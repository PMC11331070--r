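# Shared fixtures and independent oracles for the test suite.

# Small, fast generator configuration for structural tests.
small_config <- function(seed = 1, ...) {
  generator_config(n_patches = 80, extent_km = c(20, 25), n_years = 4,
                   n_loci = 30, seed = seed, ...)
}

# Hand-built genotype table: loci as a matrix of 0/1/2/NA.
toy_genotypes <- function(calls, nest_id = "n1", patch_id = "p1", year = 1) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  df <- data.frame(individual_id = paste0("ind", seq_len(n)),
                   nest_id = rep_len(nest_id, n),
                   patch_id = rep_len(patch_id, n),
                   year = rep_len(year, n),
                   stringsAsFactors = FALSE)
  colnames(calls) <- sprintf("locus_%04d", seq_len(ncol(calls)))
  cbind(df, as.data.frame(calls))
}

# Independent per-locus heterozygosity oracle: straightforward loops,
# no shared code with the vectorized implementation.
oracle_het <- function(calls) {
  he_l <- ho_l <- numeric(0)
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    n <- length(g)
    if (n < 2) next
    p <- sum(g) / (2 * n)
    ho <- mean(g == 1)
    he <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
    he_l <- c(he_l, max(he, 0))
    ho_l <- c(ho_l, ho)
  }
  c(he = mean(he_l), ho = mean(ho_l))
}

# Brute-force incidence-function connectivity: O(n^2) double loop.
oracle_connectivity <- function(xy, n_prev, alpha = 1) {
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || n_prev[j] == 0) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      s[i] <- s[i] + exp(-alpha * d) * n_prev[j]
    }
  }
  s
}

# Minimal hand-built patch/survey/het tables for covariate tests:
# 3 patches, fall years 1..5 and matching springs.
tiny_landscape <- function() {
  patches <- data.frame(
    patch_id = c("A", "B", "C"),
    x_km = c(0, 1, 2), y_km = c(0, 0, 0),
    area = c(1, 2, 0.5), host_abundance = c(2, 3, 1),
    prop_dry = c(0.1, 0.2, 0.3), prop_low_veg = c(0.5, 0.6, 0.4),
    prop_grazed = c(0, 0.1, 0.2), region = "west",
    stringsAsFactors = FALSE)
  fall <- expand.grid(patch_id = c("A", "B", "C"), year = 1:5,
                      stringsAsFactors = FALSE)
  fall$season <- "fall"
  counts <- rbind(A = c(4, 5, 3, 2, 2),
                  B = c(10, 8, 9, 7, 6),
                  C = c(0, 2, 1, 0, 1))
  fall$nest_count <- counts[cbind(match(fall$patch_id, rownames(counts)),
                                  fall$year)]
  spring <- fall
  spring$season <- "spring"
  scounts <- rbind(A = c(2, 3, 2, 1, 1),
                   B = c(6, 5, 6, 4, 3),
                   C = c(0, 1, 0, 0, 1))
  spring$nest_count <- scounts[cbind(match(spring$patch_id, rownames(scounts)),
                                     spring$year)]
  survey <- rbind(fall, spring)
  het <- expand.grid(unit_id = c("A", "B", "C"), year = 1:5,
                     stringsAsFactors = FALSE)
  het$level <- "population"
  het$he <- c(0.25, 0.35, 0.15) + 0.01 * het$year
  het$ho <- het$he
  het$n_individuals <- 6L
  het$n_loci_used <- 30L
  list(patches = patches, survey = survey, het = het)
}
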