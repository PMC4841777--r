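test_that("production follows the allometric law with a commitment gate", {
  p <- model_params()
  expect_equal(cdkg1_production(100, p), 0)  # below commitment size
  p_low <- model_params(production_coeff = 1, production_exponent = 1,
                        commitment_size = 50)
  expect_equal(cdkg1_production(100, p_low), 100)
  # concentration ratio between 4-fold different mothers is (4)^(b-1)
  p_b <- model_params(production_coeff = 0.01, production_exponent = 1.5,
                      commitment_size = 50)
  conc <- cdkg1_production(c(100, 400), p_b) / c(100, 400)
  expect_equal(conc[2] / conc[1], 2)
  expect_error(cdkg1_production(-5, p), "positive")
})

test_that("parameter validation names the offending field", {
  expect_error(model_params(degradation_fraction = 1.2),
               "degradation_fraction")
  expect_error(model_params(exit_threshold = 0), "exit_threshold")
  expect_error(model_params(production_exponent = -1),
               "production_exponent")
})

test_that("committed mothers divide at least once; uncommitted never", {
  p <- model_params()
  # a mother just past commitment whose ratio is already below threshold
  m <- mother_state(200, p, cdkg1_total = 0.1)
  out <- run_division_series(m, p)
  expect_equal(out$n_rounds, 1)
  expect_equal(out$n_daughters, 2)
  un <- mother_state(150, p)
  expect_equal(run_division_series(un, p)$n_rounds, 0)
})

test_that("conservation: per-DNA ratio exactly halves each round at delta = 0", {
  p <- model_params(degradation_fraction = 0)
  m <- mother_state(600, p)
  out <- run_division_series(m, p)
  r <- out$trajectory$per_dna_ratio
  expect_equal(r[-1] / r[-length(r)], rep(0.5, length(r) - 1))
})

test_that("per-round closed forms hold in geometric mode", {
  p <- model_params(degradation_fraction = 0.1)
  m <- mother_state(600, p)
  out <- run_division_series(m, p)
  tr <- out$trajectory
  expect_gte(nrow(tr), 3)
  expect_equal(tr$per_dna_ratio[-nrow(tr)] / tr$per_dna_ratio[-1],
               rep(2 / 0.9, nrow(tr) - 1))
  expect_equal(tr$concentration[-1] / tr$concentration[-nrow(tr)],
               rep(0.9, nrow(tr) - 1))
})

test_that("division series matches the step-by-step oracle for rounds 1-5", {
  p <- model_params()
  # stocks chosen to span outcomes from 1 to 5 completed rounds
  for (stock in c(0.5, 1.2, 3, 7, 16, 36, 80)) {
    m <- mother_state(600, p, cdkg1_total = stock,
                      total_nuclear_volume = 30)
    out <- suppressWarnings(run_division_series(m, p))
    orc <- step_oracle_series(stock, 0.1, 1, max_rounds = 5,
                              nuclear_volume = 30)
    expect_equal(out$n_rounds, orc$n_rounds, info = paste("stock", stock))
    expect_equal(out$trajectory, orc$trajectory,
                 info = paste("stock", stock))
  }
})

test_that("division count is monotone in mother volume", {
  p <- model_params()
  set.seed(5)
  v <- sort(runif(60, 100, 1200))
  n <- vapply(v, function(M)
    run_division_series(mother_state(M, p), p)$n_rounds, integer(1))
  expect_true(all(diff(n) >= 0))
})

test_that("trajectory invariants: non-increasing totals, strict per-DNA decline", {
  p <- model_params()
  for (M in c(250, 480, 700, 900)) {
    out <- run_division_series(mother_state(M, p), p)
    tr <- out$trajectory
    expect_equal(out$n_daughters, 2^out$n_rounds)
    expect_equal(out$daughter_volume * out$n_daughters, M)
    totals <- tr$per_nucleus_amount * tr$nuclei
    expect_true(all(diff(totals) <= 1e-12))
    expect_true(all(diff(tr$per_dna_ratio) < 0))
  }
})

test_that("unit accounting matches its brute-force oracle for U = 0..31", {
  expect_equal(unit_accounting_rounds(0),
               list(n_rounds = 0L, n_daughters = 1L, total_mitoses = 0L))
  expect_equal(unit_accounting_rounds(1)$n_rounds, 1L)
  expect_equal(unit_accounting_rounds(2)$n_rounds, 1L)
  expect_equal(unit_accounting_rounds(7),
               list(n_rounds = 3L, n_daughters = 8L, total_mitoses = 7L))
  for (u in 0:31) {
    orc <- unit_oracle(u)
    got <- unit_accounting_rounds(u)
    expect_equal(got$n_rounds, orc$n_rounds, info = paste("U =", u))
    expect_equal(got$n_daughters, orc$n_daughters)
    expect_equal(got$total_mitoses, orc$total_mitoses)
  }
})

test_that("unit-mode division series reproduces unit accounting exhaustively", {
  p <- model_params(unit_mode = TRUE, exit_threshold = 1,
                    sensed_quantity = "per_nucleus_amount",
                    max_rounds = 6)
  for (u in 0:31) {
    m <- mother_state(600, p, cdkg1_total = u)
    out <- run_division_series(m, p)
    expect_equal(out$n_rounds, unit_accounting_rounds(u)$n_rounds,
                 info = paste("U =", u))
  }
})

test_that("genotype scenarios shift division counts in opposite directions", {
  base <- model_params()
  expect_identical(scenario_params("wild_type", base), base)
  pn <- scenario_params("cdkg1_null", base)
  po <- scenario_params("overexpression", base)
  for (M in c(600, 848)) {   # mothers doing >= 3 wild-type rounds
    nw <- run_division_series(mother_state(M, base), base)$n_rounds
    nn <- run_division_series(mother_state(M, pn), pn)$n_rounds
    no <- run_division_series(mother_state(M, po), po)$n_rounds
    expect_lt(nn, nw)
    expect_gt(no, nw)
  }
  expect_error(scenario_params("mystery"), "unknown genotype")
})

test_that("parameter recovery succeeds on clean data and flags a bad grid", {
  p <- model_params()
  set.seed(21)
  vols <- exp(runif(80, log(200), log(1000)))
  n <- vapply(vols, function(M)
    run_division_series(mother_state(M, p), p)$n_rounds, integer(1))
  obs <- data.frame(mother_volume = vols, n_rounds = n)
  grid <- list(theta = seq(0.5, 2, length.out = 7),
               delta = seq(0, 0.3, length.out = 7),
               b = seq(1.2, 1.8, length.out = 7))
  fit <- fit_params(obs, grid, seed = 2, base = p)
  # noise-free: recovered counts reproduce the data
  pred <- vapply(vols, function(M) {
    run_division_series(mother_state(M, fit$params), fit$params)$n_rounds
  }, integer(1))
  expect_equal(pred, n)
  expect_false(fit$diagnostics$elevated_loss)
  # grid excluding the truth: best-in-grid with elevated loss flagged
  bad <- fit_params(obs, list(theta = c(40, 80), delta = c(0.8, 0.9),
                              b = c(0.3, 0.5)), seed = 2, base = p)
  expect_true(bad$diagnostics$elevated_loss)
  expect_error(fit_params(obs[1:5, ], grid), "at least 20")
})

test_that("recovery study restores theta, delta and b from noisy data", {
  r <- parameter_recovery_study(seed = 20160325 %% 1000)
  expect_lt(r$relative_error[["theta"]], 0.10)
  expect_lt(r$relative_error[["delta"]], 0.10)
  expect_lt(r$relative_error[["b"]], 0.10)
})
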