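#' Growth configuration for the diurnal simulator
#'
#' @param light_hours Hours of light available for growth (default 14, a
#'   full diurnal light period).
#' @param size_doubling_time Volume doubling time in hours (default 4.0);
#'   with 14 h of light this gives a `2^3.5 ~ 11.3`-fold size increase,
#'   matching the more-than-ten-fold growth seen over one light period.
#' @param growth_noise_cv Cell-to-cell coefficient of variation of the
#'   multiplicative (lognormal) growth noise, in `[0, 1)`.
#' @param dark_shift_hour Hour at which the culture is shifted to the
#'   dark, stopping growth; `NULL` for no early shift.
#' @param seed Integer seed for the growth noise.
#' @return A validated list of class `"growth_config"`.
#' @export
growth_config <- function(light_hours = 14, size_doubling_time = 4.0,
                          growth_noise_cv = 0.1, dark_shift_hour = NULL,
                          seed = 1) {
  stopifnot(light_hours >= 0, size_doubling_time > 0,
            growth_noise_cv >= 0, growth_noise_cv < 1,
            is.null(dark_shift_hour) || dark_shift_hour >= 0)
  structure(list(light_hours = light_hours,
                 size_doubling_time = size_doubling_time,
                 growth_noise_cv = growth_noise_cv,
                 dark_shift_hour = dark_shift_hour,
                 seed = as.integer(seed)),
            class = "growth_config")
}

#' Construct a table of cell records
#'
#' @param volume Cell volumes in cubic micrometres (> 0).
#' @param population Population label (e.g. `"I"`, `"II"`, `"III"`).
#' @param genotype Genotype label.
#' @param commitment_size Commitment size used to set the `committed`
#'   flag.
#' @return A data frame with columns `cell_id`, `volume_um3`,
#'   `committed`, `division_count`, `population`, `genotype`.
#' @export
cell_records <- function(volume, population = "custom",
                         genotype = "wild_type", commitment_size = 195) {
  stopifnot(is.numeric(volume), all(is.finite(volume)), all(volume > 0))
  data.frame(cell_id = sprintf("c%05d", seq_along(volume)),
             volume_um3 = volume,
             committed = volume >= commitment_size,
             division_count = 0L,
             population = population,
             genotype = genotype,
             stringsAsFactors = FALSE)
}

# mean-1 multiplicative lognormal noise for a given CV
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Grow a population of daughters through the light period
#'
#' Volumes grow exponentially, `V * 2^(t / size_doubling_time)`, with
#' `t` the time in the light (`min(light_hours, dark_shift_hour)`);
#' growth stops at a dark shift and newborn daughters do not grow in the
#' dark.  Multiplicative lognormal noise with the configured CV is
#' applied per cell, and the commitment flag is set for cells at or above
#' the commitment size.
#'
#' @param daughters Cell records as from [cell_records()].
#' @param cfg A [growth_config()].
#' @param params A [model_params()] (for the commitment size).
#' @return The grown cell records.
#' @export
grow_population <- function(daughters, cfg = growth_config(),
                            params = model_params()) {
  stopifnot(is.data.frame(daughters), all(daughters$volume_um3 > 0))
  t <- cfg$light_hours
  if (!is.null(cfg$dark_shift_hour)) t <- min(t, cfg$dark_shift_hour)
  set.seed(cfg$seed)
  fold <- 2^(t / cfg$size_doubling_time) *
    lognormal_noise(nrow(daughters), cfg$growth_noise_cv)
  daughters$volume_um3 <- daughters$volume_um3 * fold
  daughters$committed <- daughters$volume_um3 >= params$commitment_size
  daughters
}

#' Divide every committed mother in a population
#'
#' Runs [run_division_series()] on each cell, records the division count
#' on the mothers and collects the daughters (each mother of volume `M`
#' dividing `n` times yields `2^n` daughters of volume `M / 2^n`).
#'
#' @param mothers Cell records (grown mothers).
#' @param params A [model_params()].
#' @return A list with `mothers` (division counts filled in) and
#'   `daughters` (new cell records inheriting population and genotype).
#' @export
divide_population <- function(mothers, params = model_params()) {
  stopifnot(is.data.frame(mothers))
  n <- nrow(mothers)
  counts <- integer(n)
  d_vol <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mother_state(mothers$volume_um3[i], params,
                      committed = mothers$committed[i])
    out <- run_division_series(m, params)
    counts[i] <- out$n_rounds
    d_vol[[i]] <- rep(out$daughter_volume, out$n_daughters)
  }
  mothers$division_count <- counts
  vols <- unlist(d_vol)
  daughters <- cell_records(vols,
                            population = mothers$population[1],
                            genotype = mothers$genotype[1],
                            commitment_size = params$commitment_size)
  daughters$committed <- FALSE      # newborns are pre-commitment
  list(mothers = mothers, daughters = daughters)
}

#' Dark-shift experiment on three sub-populations
#'
#' Reproduces the classic design for making different-sized mothers from
#' one synchronous culture: the culture is split three ways, the first
#' part dark-shifted before commitment (population I, non-dividers), the
#' second dark-shifted mid-light-period to make small mothers (II), and
#' the third left in the light for the full period to make large mothers
#' (III).  Each population is grown, divided, and summarised: division
#' count histograms plus the total regulator normalised per biomass
#' (equal-protein-load analogue) and per cell (equal-cell-number
#' analogue).
#'
#' @param base_daughters Cell records for the starting daughters.
#' @param cfgs Named list of three [growth_config()]s (`I`, `II`, `III`);
#'   defaults to dark shifts at 3 h and 7 h and a full 14 h light period,
#'   with per-population seeds derived from `seed`.
#' @param params A [model_params()].
#' @param seed Base seed for the seed-split scheme used when `cfgs` is
#'   not supplied.
#' @return A list with `mothers` and `daughters` (per-population cell
#'   records), `histograms` (per-population division-category fractions)
#'   and `cdkg1_summary` (per-population regulator totals per biomass and
#'   per cell).
#' @export
dark_shift_experiment <- function(base_daughters, cfgs = NULL,
                                  params = model_params(), seed = 1) {
  stopifnot(is.data.frame(base_daughters), nrow(base_daughters) >= 3)
  if (is.null(cfgs)) {
    cfgs <- list(
      I   = growth_config(light_hours = 14, dark_shift_hour = 3,
                          seed = seed + 101L),
      II  = growth_config(light_hours = 14, dark_shift_hour = 7,
                          seed = seed + 102L),
      III = growth_config(light_hours = 14, dark_shift_hour = NULL,
                          seed = seed + 103L))
  }
  stopifnot(length(cfgs) == 3)
  labs <- names(cfgs)
  idx <- rep_len(seq_len(3), nrow(base_daughters))
  mothers <- daughters <- stats::setNames(vector("list", 3), labs)
  histograms <- stats::setNames(vector("list", 3), labs)
  summ <- data.frame(population = labs, n_cells = NA_integer_,
                     cdkg1_per_biomass = NA_real_,
                     cdkg1_per_cell = NA_real_)
  for (k in seq_len(3)) {
    part <- base_daughters[idx == k, , drop = FALSE]
    part$population <- labs[k]
    grown <- grow_population(part, cfgs[[k]], params)
    div <- divide_population(grown, params)
    mothers[[k]] <- div$mothers
    daughters[[k]] <- div$daughters
    histograms[[k]] <- division_histogram(div$mothers)
    amount <- cdkg1_production(grown$volume_um3, params)
    summ$n_cells[k] <- nrow(grown)
    summ$cdkg1_per_biomass[k] <- sum(amount) / sum(grown$volume_um3)
    summ$cdkg1_per_cell[k] <- mean(amount)
  }
  list(mothers = mothers, daughters = daughters,
       histograms = histograms, cdkg1_summary = summ)
}

#' Division-number category fractions
#'
#' Tallies division counts into the categories 0 (no division,
#' pre-commitment), 1 (two daughters), 2 (four daughters) and 3+ (eight
#' or more daughters), as fractions of the population.
#'
#' @param cells Cell records with a `division_count` column.
#' @return Named numeric vector over categories `0`, `1`, `2`, `3+`,
#'   summing to 1.
#' @export
division_histogram <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    stop("empty cell table", call. = FALSE)
  }
  n <- cells$division_count
  stopifnot(all(n >= 0))
  cat <- cut(n, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  out <- as.numeric(table(cat)) / length(n)
  names(out) <- c("0", "1", "2", "3+")
  out
}

#' Coulter-style volume distribution summary
#'
#' @param cells Cell records with a `volume_um3` column.
#' @param bin_edges Strictly increasing histogram bin edges in cubic
#'   micrometres; defaults to 30 equal bins spanning the data.
#' @return A list with `histogram` (data frame `bin_left`, `bin_right`,
#'   `count`), `median`, `mean`, `sd` and `n`.
#' @export
size_distribution <- function(cells, bin_edges = NULL) {
  if (!is.data.frame(cells) || nrow(cells) < 1) {
    stop("at least one cell is required", call. = FALSE)
  }
  v <- cells$volume_um3
  if (is.null(bin_edges)) {
    bin_edges <- seq(0, max(v) * 1.05 + 1e-9, length.out = 31)
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  }
  counts <- as.numeric(table(cut(v, breaks = bin_edges,
                                 include.lowest = TRUE)))
  list(histogram = data.frame(bin_left = utils::head(bin_edges, -1),
                              bin_right = bin_edges[-1],
                              count = counts),
       median = stats::median(v), mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v))
}
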