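test_that("generator configuration validates its inputs", {
  expect_error(generator_config(n_patches = 1), "n_patches")
  expect_error(generator_config(extent_km = c(-1, 10)), "extent")
  expect_error(generator_config(founder_maf_range = c(0, 0.5)), "maf")
  expect_error(generator_config(founder_maf_range = c(0.1, 0.6)), "maf")
  expect_error(generator_config(target_occupancy = 1.5), "occupancy")
  expect_error(generator_config(s0 = 0), "s0")
  expect_error(generator_config(missing_call_rate = 1.2), "call_rate")
  cfg <- generator_config(n_years = 2)
  expect_error(simulate_dynamics(generate_patches(cfg), cfg), "n_years")
})

test_that("patch placement is bounded, reproducible, and spatially uniform", {
  cfg <- generator_config(n_patches = 100, seed = 1)
  p <- generate_patches(cfg)
  expect_equal(nrow(p), 100)
  expect_true(all(p$x_km >= 0 & p$x_km <= cfg$extent_km[1]))
  expect_true(all(p$y_km >= 0 & p$y_km <= cfg$extent_km[2]))
  expect_true(all(p$host_abundance %in% 1:3))
  expect_true(all(p$area > 0))
  expect_identical(p, generate_patches(generator_config(n_patches = 100, seed = 1)))

  # mean nearest-neighbour distance of a uniform point process is
  # 0.5 / sqrt(density); check the large-n placement against it
  cfg4k <- generator_config(n_patches = 4000, extent_km = c(50, 70), seed = 3)
  p4k <- generate_patches(cfg4k)
  d <- as.matrix(dist(cbind(p4k$x_km, p4k$y_km)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expected <- 0.5 / sqrt(4000 / (50 * 70))
  expect_lt(abs(mean(nn) - expected) / expected, 0.10)
})

test_that("offspring heterozygosity follows the Mendelian expectation for every parental pair", {
  set.seed(7)
  n <- 40000
  for (g1 in 0:2) {
    for (g2 in 0:2) {
      off <- metahet:::.mendelian_offspring(rep(g1, n), rep(g2, n))
      p1 <- g1 / 2
      p2 <- g2 / 2
      p_het <- p1 * (1 - p2) + p2 * (1 - p1)
      se <- sqrt(max(p_het * (1 - p_het), 1e-12) / n)
      expect_lt(abs(mean(off == 1) - p_het), 3 * se + 1e-9)
      # allele-count mean: p1 + p2
      expect_lt(abs(mean(off) - (p1 + p2)), 3 * sqrt(0.5 / n) + 1e-9)
    }
  }
})

test_that("parent genotypes show the requested heterozygote deficit", {
  set.seed(8)
  p <- 0.4
  for (f in c(0, 0.5)) {
    g <- metahet:::.draw_parent_genotypes(rep(p, 50000), f)
    p_het <- 2 * p * (1 - p) * (1 - f)
    expect_lt(abs(mean(g == 1) - p_het), 3 * sqrt(p_het * (1 - p_het) / 50000))
  }
})

test_that("simulated nest survival matches s0 * exp(-B * F) across inbreeding deciles", {
  cfg <- generator_config(seed = 5)
  sim <- simulate_dynamics(generate_patches(cfg), cfg)
  nests <- sim$nests
  dec <- cut(nests$f_true, breaks = unique(quantile(nests$f_true, 0:10 / 10)),
             include.lowest = TRUE)
  for (lev in levels(dec)) {
    grp <- nests[dec == lev, ]
    if (nrow(grp) < 30) next
    pred <- mean(cfg$s0 * exp(-cfg$b_true * grp$f_true))
    obs <- mean(grp$survived_overwinter)
    se <- sqrt(pred * (1 - pred) / nrow(grp))
    expect_lt(abs(obs - pred), 3 * se + 1e-9)
  }
})

test_that("with no inbreeding load, nest survival is the baseline s0", {
  cfg <- small_config(seed = 2, b_true = 0)
  sim <- simulate_dynamics(generate_patches(cfg), cfg)
  n <- nrow(sim$nests)
  se <- sqrt(cfg$s0 * (1 - cfg$s0) / n)
  expect_lt(abs(mean(sim$nests$survived_overwinter) - cfg$s0), 3 * se)
})

test_that("identical config and seed give identical datasets; different seeds differ", {
  cfg <- small_config(seed = 9)
  a <- simulate_dynamics(generate_patches(cfg), cfg)
  b <- simulate_dynamics(generate_patches(cfg), cfg)
  expect_identical(a, b)
  cfg2 <- small_config(seed = 10)
  c2 <- simulate_dynamics(generate_patches(cfg2), cfg2)
  expect_false(identical(a$genotypes, c2$genotypes))
})

test_that("survey tables obey the no-overwinter-births invariant", {
  cfg <- small_config(seed = 3)
  sim <- simulate_dynamics(generate_patches(cfg), cfg)
  w <- merge(sim$survey[sim$survey$season == "fall", ],
             sim$survey[sim$survey$season == "spring", ],
             by = c("patch_id", "year"))
  expect_true(all(w$nest_count.y <= w$nest_count.x))
  expect_true(all(sim$survey$nest_count >= 0))
  expect_true(all(sim$nests$n_families >= 1))
  expect_true(all(sim$nests$f_true >= 0 & sim$nests$f_true <= 1))
})

test_that("datasets round-trip losslessly through write_dataset/read_dataset", {
  cfg <- small_config(seed = 4)
  patches <- generate_patches(cfg)
  sim <- simulate_dynamics(patches, cfg)
  dir <- file.path(tempdir(), "metahet-roundtrip")
  write_dataset(sim, patches, cfg, dir)
  back <- read_dataset(dir)
  expect_equal(back$patches, patches, tolerance = 1e-12)
  expect_equal(back$survey, sim$survey)
  expect_equal(back$nests, sim$nests, tolerance = 1e-12)
  expect_equal(back$genotypes, sim$genotypes)
  expect_equal(back$config$seed, cfg$seed)

  # a different seed must produce different genotype files
  cfg2 <- small_config(seed = 5)
  sim2 <- simulate_dynamics(generate_patches(cfg2), cfg2)
  dir2 <- file.path(tempdir(), "metahet-roundtrip2")
  write_dataset(sim2, generate_patches(cfg2), cfg2, dir2)
  expect_false(identical(readLines(file.path(dir, "genotypes.csv")),
                         readLines(file.path(dir2, "genotypes.csv"))))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("without rescue, annual and overwinter extinction coincide patch for patch", {
  cfg <- small_config(seed = 6, rescue_scale = 0)
  sim <- simulate_dynamics(generate_patches(cfg), cfg)
  fall <- sim$survey[sim$survey$season == "fall", ]
  spring <- sim$survey[sim$survey$season == "spring", ]
  for (t in seq_len(cfg$n_years - 1)) {
    f <- fall[fall$year == t, ]
    s <- spring[spring$year == t, ]
    fn <- fall[fall$year == t + 1, ]
    m <- Reduce(function(a, b) merge(a, b, by = "patch_id"), list(f, s, fn))
    occ <- m$nest_count.x > 0
    expect_identical(occ & m$nest_count.y == 0, occ & m$nest_count == 0)
  }
})
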