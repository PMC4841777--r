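# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths: plain double loops and exhaustive
# enumeration.

# per-label background-subtracted pixel sums by explicit iteration
brute_force_measure <- function(ha, labels, background = 0) {
  k <- max(labels)
  sums <- numeric(k)
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(ncol(ha))) {
      l <- labels[i, j]
      if (l > 0) {
        sums[l] <- sums[l] + max(ha[i, j] - background, 0)
      }
    }
  }
  sums
}

# step-by-step division series for the geometric model: recomputes every
# round from first principles, sensing the per-genome ratio before each
# round; committed cells always divide once
step_oracle_series <- function(stock, delta, theta, max_rounds = 5,
                               nuclear_volume = 30) {
  total <- stock
  nuclei <- 1
  rows <- NULL
  n <- 0
  for (r in seq_len(max_rounds)) {
    if (r > 1 && total / nuclei < theta) break
    nuclei <- nuclei * 2
    total <- total * (1 - delta)
    n <- r
    rows <- rbind(rows, data.frame(
      round = r, nuclei = nuclei,
      per_nucleus_amount = total / nuclei,
      concentration = total / nuclear_volume,
      per_dna_ratio = total / nuclei))
  }
  list(n_rounds = n, trajectory = rows)
}

# brute-force unit accounting: pay one unit per nucleus present, round
# by round, until a round cannot be fully paid for
unit_oracle <- function(units) {
  n <- 0
  nuclei <- 1
  left <- units
  repeat {
    if (left < nuclei) break
    left <- left - nuclei
    nuclei <- nuclei * 2
    n <- n + 1
  }
  list(n_rounds = n, n_daughters = 2^n, total_mitoses = 2^n - 1)
}

# exhaustive-permutation two-sided p-value for the Mann-Whitney U
# statistic (tie-free data)
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), 1))
  }
  u_obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
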