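make_disk <- function(side, cy, cx, r) {
  rows <- matrix(rep(seq_len(side), side), side, side)
  cols <- matrix(rep(seq_len(side), each = side), side, side)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

test_that("segmentation finds disjoint disks with exact areas", {
  img <- matrix(0, 40, 40)
  d1 <- make_disk(40, 10, 10, 5)
  d2 <- make_disk(40, 30, 30, 3)
  img[d1] <- 1
  img[d2] <- 1
  seg <- segment_nuclei(img, pixel_size = 0.2)
  expect_equal(length(seg$areas), 2)
  expect_equal(sort(unname(seg$areas)),
               sort(c(sum(d1), sum(d2)) * 0.2^2))
  # min_area filter drops the small disk
  seg2 <- segment_nuclei(img, pixel_size = 0.2,
                         min_area = sum(d2) * 0.2^2 + 0.01)
  expect_equal(length(seg2$areas), 1)
})

test_that("segmentation handles blank and saturated images per contract", {
  blank <- matrix(0, 10, 10)
  seg <- segment_nuclei(blank, pixel_size = 0.1)
  expect_equal(length(seg$areas), 0)
  expect_error(segment_nuclei(matrix(3, 10, 10), pixel_size = 0.1),
               "threshold failure")
})

test_that("labelling is 8-connected", {
  img <- matrix(0, 8, 8)
  img[cbind(c(2, 3, 4), c(2, 3, 4))] <- 1  # diagonal chain
  seg <- segment_nuclei(img, pixel_size = 1)
  expect_equal(length(seg$areas), 1)
  expect_equal(unname(seg$areas), 3)
})

test_that("nucleus measurement equals the brute-force pixel oracle", {
  set.seed(13)
  labels <- matrix(0L, 25, 25)
  labels[make_disk(25, 7, 7, 4)] <- 1L
  labels[make_disk(25, 18, 18, 5)] <- 2L
  ha <- matrix(runif(625, 0, 10), 25, 25)
  for (bg in c(0, 2.5)) {
    m <- measure_nuclei(ha, labels, pixel_size = 0.1, background = bg)
    expect_equal(m$intensity_sum, brute_force_measure(ha, labels, bg))
  }
  # uniform signal at background level sums to zero
  m0 <- measure_nuclei(matrix(2, 25, 25), labels, 0.1, background = 2)
  expect_equal(m0$intensity_sum, c(0, 0))
  # a 100-pixel nucleus at background + 5 sums to 500
  lab1 <- matrix(0L, 20, 20)
  lab1[1:10, 1:10] <- 1L
  m5 <- measure_nuclei(matrix(7, 20, 20), lab1, 0.1, background = 2)
  expect_equal(m5$intensity_sum, 500)
  expect_error(measure_nuclei(matrix(0, 3, 3), matrix(0L, 4, 4), 0.1),
               "shape")
})

test_that("stage summaries recover scheduled means and apply filters", {
  cfg <- synthetic_config(seed = 17, n_cells = 80,
                          intensity_noise_cv = 0.1)
  rec <- gen_if_records(cfg)
  sm <- stage_summaries(rec$cells, min_cells_per_stage = 68,
                        params = model_params())
  expect_equal(sm$n, rep(80, 5))
  expect_false(any(sm$flagged))
  for (i in seq_len(nrow(sm))) {
    se <- sm$sd[i] / sqrt(sm$n[i])
    expect_lt(abs(sm$mean[i] - rec$truth$true_concentration_mean[i]),
              3 * se + 1e-9)
  }
  # identical cells: sd 0
  one <- data.frame(stage = 2, mean_nucleus_concentration = rep(3, 70))
  s1 <- stage_summaries(one, min_cells_per_stage = 68)
  expect_equal(s1$sd, 0)
  expect_error(stage_summaries(one[1:5, ], min_cells_per_stage = 68),
               "min_cells_per_stage")
})

test_that("per-DNA series is the conservation sequence at delta = 0", {
  cfg <- synthetic_config(seed = 2, n_cells = 10,
                          degradation_fraction = 0,
                          intensity_noise_cv = 0)
  rec <- gen_if_records(cfg)
  s <- per_dna_series(rec$cells)
  expect_equal(s$normalized, (1 / 2)^(0:4))
  # delta = 0.1: successive factor (1 - 0.1)/2 = 0.45
  cfg2 <- synthetic_config(seed = 2, n_cells = 10,
                           degradation_fraction = 0.1,
                           intensity_noise_cv = 0)
  s2 <- per_dna_series(gen_if_records(cfg2)$cells)
  expect_equal(s2$normalized[-1] / s2$normalized[-5], rep(0.45, 4))
  expect_error(per_dna_series(rec$cells[rec$cells$stage == 1, ]),
               "two stages")
})

test_that("stage-mean OLS reports slope, intercept and R squared", {
  f <- linear_fit_means(c(4, 3, 2, 1))
  expect_equal(f$slope, -1)
  expect_equal(f$r_squared, 1)
  exact <- c(10, 8, 6)      # collinear
  expect_equal(linear_fit_means(exact)$r_squared, 1)
  # hand-evaluated R^2 for a perturbed point
  y <- c(4, 3, 2 + 0.3, 1)
  x <- 1:4
  fit <- linear_fit_means(y)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  r2_hand <- 1 - sum((y - alpha - beta * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2_hand)
  expect_equal(fit$slope, beta)
  expect_error(linear_fit_means(c(1, 2)), "three")
})

test_that("rank-sum comparison: exact small-sample p matches enumeration", {
  r <- compare_stages(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)
  expect_equal(unname(r$statistic), 0)
  # identical tied groups: z = 0, two-sided p = 1
  expect_equal(compare_stages(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(19)
  for (i in 1:10) {
    na <- sample(3:4, 1)
    nb <- sample(3:4, 1)
    x <- sample(seq(1, 40), na + nb)  # tie-free
    a <- x[seq_len(na)]
    b <- x[-seq_len(na)]
    expect_equal(compare_stages(a, b)$p_value, perm_mw_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(compare_stages(1:2, 1:5), "at least 3")
})

test_that("rank-sum on synthetic 2- vs 8-nuclei concentrations is significant", {
  cfg <- synthetic_config(seed = 23, n_cells = 68,
                          intensity_noise_cv = 0.1)
  rec <- gen_if_records(cfg)
  a <- rec$cells$mean_nucleus_concentration[rec$cells$stage == 2]
  b <- rec$cells$mean_nucleus_concentration[rec$cells$stage == 8]
  expect_lt(compare_stages(a, b)$p_value, 0.005)
})

test_that("one-way ANOVA matches hand computation and the stats reference", {
  g <- list(c(1, 2, 3), c(2, 3, 4))
  r <- nc_anova(g)
  expect_equal(r$statistic, 1.5)
  ref <- summary(stats::aov(v ~ f, data.frame(
    v = unlist(g), f = factor(rep(1:2, each = 3)))))[[1]]
  expect_equal(r$statistic, ref$`F value`[1])
  expect_equal(r$p_value, ref$`Pr(>F)`[1])
  # all groups the same constant: F = 0, p = 1 by convention
  same <- nc_anova(list(rep(2, 5), rep(2, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(nc_anova(list(1:3)), "2 groups")
})

test_that("nuclear fraction scoring uses a strict one-half boundary", {
  cells <- data.frame(
    stage = c(2, 2, 2, 4),
    nuclear_fraction = c(1, 0.5, 0.7, 0.9),
    total_intensity_in_cell = c(10, 10, 10, 10))
  s <- nuclear_fraction_score(cells)
  expect_equal(s$fraction_above_half[s$stage == 2], 2 / 3)
  expect_equal(s$fraction_above_half[s$stage == 4], 1)
  # zero-total cells excluded and counted
  cells2 <- rbind(cells, data.frame(stage = 2, nuclear_fraction = NA,
                                    total_intensity_in_cell = 0))
  expect_message(s2 <- nuclear_fraction_score(cells2), "excluded")
  expect_equal(attr(s2, "n_excluded"), 1)
  expect_equal(s2$n[s2$stage == 2], 3)
})
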