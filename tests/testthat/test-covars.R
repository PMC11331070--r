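test_that("connectivity matches closed-form values", {
  p <- data.frame(patch_id = c("focal", "src"), x_km = c(0, 1), y_km = c(0, 0))
  s <- data.frame(patch_id = "src", year = 0, season = "fall", nest_count = 10)
  out <- connectivity(p, s, year = 1, alpha = 1)
  expect_equal(out$s_i[out$patch_id == "focal"], 10 * exp(-1),
               tolerance = 1e-12)

  # two sources at d = 0.5 (N = 4) and d = 2 (N = 20)
  p2 <- data.frame(patch_id = c("focal", "a", "b"),
                   x_km = c(0, 0.5, 2), y_km = 0)
  s2 <- data.frame(patch_id = c("a", "b"), year = 0, season = "fall",
                   nest_count = c(4, 20))
  out2 <- connectivity(p2, s2, year = 1)
  expect_equal(out2$s_i[out2$patch_id == "focal"],
               4 * exp(-0.5) + 20 * exp(-2), tolerance = 1e-12)

  # no occupied sources -> S = 0 everywhere
  s0 <- data.frame(patch_id = c("a", "b"), year = 0, season = "fall",
                   nest_count = 0)
  expect_true(all(connectivity(p2, s0, year = 1)$s_i == 0))

  # missing prior-year fall survey is an error
  expect_error(connectivity(p2, s2, year = 5), "prior fall")
})

test_that("connectivity equals the brute-force double loop on random landscapes", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    counts <- rpois(n, 2)
    alpha <- runif(1, 0.3, 2)
    p <- data.frame(patch_id = paste0("p", seq_len(n)),
                    x_km = xy[, 1], y_km = xy[, 2])
    s <- data.frame(patch_id = p$patch_id, year = 3, season = "fall",
                    nest_count = counts)
    out <- connectivity(p, s, year = 4, alpha = alpha)
    expect_equal(out$s_i, oracle_connectivity(xy, counts, alpha),
                 tolerance = 1e-10)
  }
})

test_that("adding an occupied source never decreases connectivity", {
  set.seed(22)
  n <- 12
  p <- data.frame(patch_id = paste0("p", 1:n),
                  x_km = runif(n, 0, 5), y_km = runif(n, 0, 5))
  counts <- rpois(n, 1.5)
  s <- data.frame(patch_id = p$patch_id, year = 1, season = "fall",
                  nest_count = counts)
  base <- connectivity(p, s, year = 2)
  counts2 <- counts
  empty <- which(counts == 0)[1]
  counts2[empty] <- 5
  s2 <- s; s2$nest_count <- counts2
  more <- connectivity(p, s2, year = 2)
  expect_true(all(more$s_i >= base$s_i - 1e-12))
})

test_that("the neighbourhood trend is the year-over-year connectivity difference", {
  s_t <- data.frame(patch_id = c("a", "b"), year = 2, s_i = c(5.0, 2.0))
  s_tm1 <- data.frame(patch_id = c("a", "b"), year = 1, s_i = c(3.2, 2.0))
  nt <- ntrend(s_t, s_tm1)
  expect_equal(nt$ntrend, c(1.8, 0))
  # a patch missing from the earlier year propagates NA
  nt2 <- ntrend(s_t, s_tm1[1, ])
  expect_true(is.na(nt2$ntrend[2]))

  # in a metapopulation-wide decline every patch trend is negative
  set.seed(23)
  n <- 15
  p <- data.frame(patch_id = paste0("p", 1:n),
                  x_km = runif(n, 0, 5), y_km = runif(n, 0, 5))
  big <- data.frame(patch_id = p$patch_id, year = 1, season = "fall",
                    nest_count = rpois(n, 6) + 1)
  small <- big; small$year <- 2; small$nest_count <- pmax(big$nest_count - 3, 0)
  survey <- rbind(big, small)
  nt3 <- ntrend(connectivity(p, survey, 3), connectivity(p, survey, 2))
  expect_true(all(nt3$ntrend < 0))
})

test_that("population trends are classified by the strict one- and two-step rules", {
  mk <- function(counts) data.frame(patch_id = "a", year = seq_along(counts),
                                    season = "fall", nest_count = counts)
  get <- function(survey, horizon, yr) {
    tr <- classify_trend(survey, horizon)
    tr$trend[tr$year == yr]
  }
  expect_equal(get(mk(c(5, 3)), 1, 2), "declined")
  expect_equal(get(mk(c(3, 5)), 1, 2), "increased")
  expect_equal(get(mk(c(4, 4)), 1, 2), "stable")      # tie = stable
  expect_equal(get(mk(c(3, 5, 4)), 2, 3), "stable")   # no directionality
  expect_equal(get(mk(c(5, 4, 3)), 2, 3), "declined")
  expect_equal(get(mk(c(3, 4, 5)), 2, 3), "increased")
  expect_equal(get(mk(c(4, 4, 4)), 2, 3), "stable")
  expect_true(is.na(get(mk(c(0, 4, 3)), 2, 3)))       # unoccupied at t - 2
  expect_true(is.na(get(mk(c(0, 3)), 1, 2)))          # unoccupied at t - 1
  expect_error(classify_trend(mk(c(1, 2)), horizon = 3), "horizon")
})

test_that("analysis tables standardize covariates on the final subset", {
  land <- tiny_landscape()
  tab <- build_analysis_table(land$patches, land$survey, land$het,
                              response = "annual_ext", model_id = 2)
  expect_true(nrow(tab) > 0)
  for (v in grep("^z_", names(tab), value = TRUE)) {
    x <- tab[[v]][!is.na(tab[[v]])]
    if (length(unique(x)) > 1) {
      expect_lt(abs(mean(x)), 1e-12)
      expect_lt(abs(sd(x) - 1), 1e-12)
    }
  }
  expect_identical(attr(tab, "response"), "annual_ext")
  # rebuilding from the same inputs is deterministic and idempotent
  tab2 <- build_analysis_table(land$patches, land$survey, land$het,
                               response = "annual_ext", model_id = 2)
  expect_identical(tab, tab2)
})

test_that("a rescued patch is overwinter-extinct but not annually extinct", {
  land <- tiny_landscape()
  # patch C in year 3: fall count 1, spring count 0, fall year 4 count 0 ->
  # overwinter extinction; patch A persists. Build year-4 rescue instead:
  # patch C year 4: fall 0 -> not in table; year 5 fall 1 after spring 0?
  ow <- build_analysis_table(land$patches, land$survey, land$het,
                             response = "overwinter_ext", model_id = 1)
  an <- build_analysis_table(land$patches, land$survey, land$het,
                             response = "annual_ext", model_id = 1)
  ow_c3 <- ow$y[ow$patch_id == "C" & ow$year == 3]
  an_c3 <- an$y[an$patch_id == "C" & an$year == 3]
  expect_equal(ow_c3, 1)   # 1 nest in fall, 0 in spring
  expect_equal(an_c3, 1)   # not rescued: fall of year 4 is empty
  # patch A in year 3: spring has survivors -> no overwinter extinction
  expect_equal(ow$y[ow$patch_id == "A" & ow$year == 3], 0)

  # construct an explicit rescue: C extinct overwinter in year 4 but
  # recolonized before the fall-5 census
  land2 <- tiny_landscape()
  f <- land2$survey$season == "fall" & land2$survey$patch_id == "C"
  s <- land2$survey$season == "spring" & land2$survey$patch_id == "C"
  land2$survey$nest_count[f & land2$survey$year == 4] <- 2
  land2$survey$nest_count[s & land2$survey$year == 4] <- 0
  land2$survey$nest_count[f & land2$survey$year == 5] <- 3
  ow2 <- build_analysis_table(land2$patches, land2$survey, land2$het,
                              response = "overwinter_ext", model_id = 1)
  an2 <- build_analysis_table(land2$patches, land2$survey, land2$het,
                              response = "annual_ext", model_id = 1)
  expect_equal(ow2$y[ow2$patch_id == "C" & ow2$year == 4], 1)
  expect_equal(an2$y[an2$patch_id == "C" & an2$year == 4], 0)
})

test_that("nest-mortality tables drop merged nests and use nest-level heterozygosity", {
  cfg <- small_config(seed = 13, merged_nest_fraction = 0.2)
  patches <- generate_patches(cfg)
  sim <- simulate_dynamics(patches, cfg)
  gt <- filter_units(filter_individuals(sim$genotypes), "nest")
  hn <- heterozygosity(gt, "nest")
  tab <- build_analysis_table(patches, sim$survey, hn, sim$nests,
                              response = "nest_mortality", model_id = 2)
  expect_true(nrow(tab) > 0)
  fams <- sim$nests$n_families[match(tab$nest_id, sim$nests$nest_id)]
  expect_true(all(fams == 1))
  expect_true(all(!is.na(tab$he)))
  expect_true(all(tab$y %in% 0:1))
})

test_that("trend-stratified models only keep rows with a defined trend", {
  land <- tiny_landscape()
  t5 <- build_analysis_table(land$patches, land$survey, land$het,
                             response = "overwinter_ext", model_id = 5)
  expect_true(all(!is.na(t5$trend_1gen)))
  t6 <- build_analysis_table(land$patches, land$survey, land$het,
                             response = "overwinter_ext", model_id = 6)
  expect_true(all(!is.na(t6$trend_2gen)))
})
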