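test_that("growth follows the closed-form fold and respects dark shift", {
  p <- model_params()
  cells <- cell_records(rep(75, 10))
  g0 <- grow_population(cells, growth_config(light_hours = 0,
                                             growth_noise_cv = 0), p)
  expect_equal(g0$volume_um3, cells$volume_um3)
  g <- grow_population(cells, growth_config(light_hours = 14,
                                            size_doubling_time = 4,
                                            growth_noise_cv = 0), p)
  expect_equal(g$volume_um3, rep(75 * 2^3.5, 10))
  expect_gte(g$volume_um3[1] / 75, 10)    # more than ten-fold
  gd <- grow_population(cells, growth_config(light_hours = 14,
                                             dark_shift_hour = 3,
                                             growth_noise_cv = 0), p)
  expect_equal(gd$volume_um3, rep(75 * 2^(3 / 4), 10))
  expect_false(any(gd$committed))
  expect_true(all(g$committed))
})

test_that("division histogram tallies categories and rejects empty input", {
  cells <- cell_records(rep(100, 4))
  cells$division_count <- c(1L, 1L, 2L, 3L)
  expect_equal(division_histogram(cells),
               c("0" = 0, "1" = 0.5, "2" = 0.25, "3+" = 0.25))
  pre <- cell_records(rep(100, 5))
  expect_equal(division_histogram(pre),
               c("0" = 1, "1" = 0, "2" = 0, "3+" = 0))
  expect_error(division_histogram(pre[0, ]), "empty")
})

test_that("size distribution summarises and validates bins", {
  one <- cell_records(42)
  s <- size_distribution(one)
  expect_equal(s$median, 42)
  expect_equal(s$mean, 42)
  expect_equal(s$sd, 0)
  expect_error(size_distribution(one, bin_edges = c(0, 10, 5)),
               "increasing")
  # lognormal sample moments match the configured mean within 3 SE
  cfg <- synthetic_config(seed = 9, n_cells = 10000,
                          daughter_volume_mean = 75,
                          daughter_volume_cv = 0.1)
  pop <- gen_size_population(cfg)
  s2 <- size_distribution(pop)
  se <- 7.5 / sqrt(10000)
  expect_lt(abs(s2$mean - 75), 3 * se)
})

test_that("dark-shift experiment reproduces the three-population design", {
  set.seed(1)
  base <- gen_size_population(synthetic_config(seed = 1, n_cells = 300))
  ex <- dark_shift_experiment(base, params = model_params(), seed = 1)
  # population I: dark-shifted before commitment, no dividing cells
  expect_equal(unname(ex$histograms$I["0"]), 1)
  # II mostly 1-2 rounds, III mostly 3-4 rounds (growth noise lets a
  # small tail of II stay pre-commitment)
  expect_gte(mean(ex$mothers$II$division_count %in% 1:2), 0.95)
  expect_gte(mean(ex$mothers$III$division_count %in% 3:4), 0.95)
  # equal-protein-load analogue: per-biomass regulator higher in III
  s <- ex$cdkg1_summary
  expect_gt(s$cdkg1_per_biomass[s$population == "III"],
            s$cdkg1_per_biomass[s$population == "II"])
  # mass bookkeeping per population: daughters conserve mother volume
  for (k in c("I", "II", "III")) {
    expect_equal(sum(ex$daughters[[k]]$volume_um3),
                 sum(ex$mothers[[k]]$volume_um3))
  }
})

test_that("pipeline is reproducible for identical seeds", {
  base <- gen_size_population(synthetic_config(seed = 4, n_cells = 90))
  e1 <- dark_shift_experiment(base, params = model_params(), seed = 11)
  e2 <- dark_shift_experiment(base, params = model_params(), seed = 11)
  expect_identical(e1, e2)
})

test_that("sharper threshold sensing tightens the daughter-size distribution", {
  p <- model_params()
  set.seed(31)
  vols <- exp(runif(400, log(250), log(900)))
  daughters_with_stock_noise <- function(cv, seed) {
    set.seed(seed)
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(length(vols), -sdlog^2 / 2, sdlog)
    } else rep(1, length(vols))
    unlist(lapply(seq_along(vols), function(i) {
      m <- mother_state(vols[i], p,
                        cdkg1_total = cdkg1_production(vols[i], p) *
                          noise[i])
      out <- run_division_series(m, p)
      rep(out$daughter_volume, out$n_daughters)
    }))
  }
  cv_of <- function(x) stats::sd(x) / mean(x)
  tight <- cv_of(daughters_with_stock_noise(0.02, 7))
  loose <- cv_of(daughters_with_stock_noise(0.5, 7))
  expect_lt(tight, loose)
})

test_that("genotype ordering of simulated daughter medians matches phenotypes", {
  base <- model_params()
  d0 <- gen_size_population(synthetic_config(seed = 6, n_cells = 200))
  med <- sapply(c("overexpression", "wild_type", "cdkg1_null"),
                function(g) {
    p <- scenario_params(g, base)
    grown <- grow_population(d0, growth_config(seed = 8), p)
    stats::median(divide_population(grown, p)$daughters$volume_um3)
  })
  expect_lt(med[["overexpression"]], med[["wild_type"]])
  expect_lt(med[["wild_type"]], med[["cdkg1_null"]])
})
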