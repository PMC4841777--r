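#' Configuration for the synthetic data generators
#'
#' Fixes the study conditions the generators emulate: daughter sizes
#' (wild-type mean 75 um^3), division stages of 1 to 16 nuclei whose
#' per-nucleus volume halves each round at constant total nuclear
#' volume, a per-stage nuclear concentration schedule that declines
#' geometrically (factor `1 - delta`) or linearly, multiplicative
#' lognormal measurement noise on sizes and intensities, and additive
#' Gaussian noise on pixels.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_cells Cells per population (or per stage for IF records).
#' @param daughter_volume_mean Mean daughter volume, um^3 (default 75).
#' @param daughter_volume_cv CV of daughter volumes (default 0.04, i.e.
#'   75 +/- 3).
#' @param stage_list Nuclei counts of the division stages; strictly
#'   increasing powers of two.
#' @param concentration_start Stage-1 mean nuclear concentration
#'   (AU per um^3).
#' @param concentration_decrement_mode `"geometric"` (factor
#'   `1 - degradation_fraction` per stage) or `"linear"` (subtract
#'   `degradation_fraction * concentration_start` per stage).
#' @param degradation_fraction Net per-round loss `delta` in `[0, 1)`.
#' @param intensity_noise_cv CV of the per-nucleus multiplicative
#'   intensity noise.
#' @param image_pixel_size Pixel edge length for rendered images, um.
#' @param total_nuclear_volume Total nuclear volume per cell, um^3,
#'   constant across stages (default 30).
#' @param cytoplasm_signal_fraction Fraction of a cell's total signal
#'   residing outside nuclei, in `[0, 1)`.
#' @param background Constant image background level (AU per pixel).
#' @param pixel_noise_cv Additive Gaussian pixel noise, as a fraction of
#'   the nuclear per-pixel amplitude.
#' @param nc_true True nucleocytoplasmic volume ratio (default 0.05).
#' @param geometry_noise_cv CV of multiplicative measurement noise on
#'   diameters and axes.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1, n_cells = 100,
                             daughter_volume_mean = 75,
                             daughter_volume_cv = 0.04,
                             stage_list = c(1, 2, 4, 8, 16),
                             concentration_start = 20,
                             concentration_decrement_mode =
                               c("geometric", "linear"),
                             degradation_fraction = 0.1,
                             intensity_noise_cv = 0.1,
                             image_pixel_size = 0.1,
                             total_nuclear_volume = 30,
                             cytoplasm_signal_fraction = 0.1,
                             background = 5,
                             pixel_noise_cv = 0,
                             nc_true = 0.05,
                             geometry_noise_cv = 0.03) {
  cvs <- c(daughter_volume_cv, intensity_noise_cv, geometry_noise_cv,
           cytoplasm_signal_fraction)
  stopifnot(all(cvs >= 0), all(cvs < 1), pixel_noise_cv >= 0,
            n_cells >= 1, daughter_volume_mean > 0,
            concentration_start > 0, image_pixel_size > 0,
            total_nuclear_volume > 0, nc_true > 0,
            degradation_fraction >= 0, degradation_fraction < 1)
  if (any(diff(stage_list) <= 0) ||
      any(abs(log2(stage_list) - round(log2(stage_list))) > 1e-9)) {
    stop("'stage_list' must be strictly increasing powers of 2",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 daughter_volume_mean = daughter_volume_mean,
                 daughter_volume_cv = daughter_volume_cv,
                 stage_list = as.integer(stage_list),
                 concentration_start = concentration_start,
                 concentration_decrement_mode =
                   match.arg(concentration_decrement_mode),
                 degradation_fraction = degradation_fraction,
                 intensity_noise_cv = intensity_noise_cv,
                 image_pixel_size = image_pixel_size,
                 total_nuclear_volume = total_nuclear_volume,
                 cytoplasm_signal_fraction = cytoplasm_signal_fraction,
                 background = background,
                 pixel_noise_cv = pixel_noise_cv,
                 nc_true = nc_true,
                 geometry_noise_cv = geometry_noise_cv),
            class = "synthetic_config")
}

# per-nucleus sphere radius (um) at a given stage, from the constant
# total nuclear volume
stage_nucleus_radius <- function(cfg, stage) {
  (3 * (cfg$total_nuclear_volume / stage) / (4 * pi))^(1 / 3)
}

# scheduled mean nuclear concentration at stage index k = log2(stage)
stage_concentration_mean <- function(cfg, stage) {
  k <- log2(stage)
  if (cfg$concentration_decrement_mode == "geometric") {
    cfg$concentration_start * (1 - cfg$degradation_fraction)^k
  } else {
    pmax(cfg$concentration_start *
           (1 - cfg$degradation_fraction * k), 0)
  }
}

#' Generate a lognormal daughter-size population
#'
#' @param cfg A [synthetic_config()].
#' @param genotype Genotype label carried on the records.
#' @return Cell records (see [cell_records()]).
#' @export
gen_size_population <- function(cfg = synthetic_config(),
                                genotype = "wild_type") {
  set.seed(cfg$seed)
  v <- cfg$daughter_volume_mean *
    lognormal_noise(cfg$n_cells, cfg$daughter_volume_cv)
  cell_records(v, population = "custom", genotype = genotype)
}

#' Generate per-cell immunofluorescence records with ground truth
#'
#' For each stage `s` in the configured stage list, draws `n_cells`
#' cells with `s` nuclei of volume `total_nuclear_volume / s` each.
#' Per-nucleus concentrations are the stage's scheduled mean times
#' multiplicative lognormal noise; intensities are concentration times
#' nuclear volume; the per-DNA ratio is total nuclear intensity over
#' nuclei count.  The scheduled (true) stage means are attached as the
#' `truth` element.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `cells` (per-cell records as consumed by
#'   [stage_summaries()] and friends), `nuclei` (per-nucleus table) and
#'   `truth` (scheduled stage means).
#' @export
gen_if_records <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed + 1L)
  vtot <- cfg$total_nuclear_volume
  mother_volume <- vtot / cfg$nc_true
  cells_list <- nuclei_list <- list()
  for (s in cfg$stage_list) {
    cmean <- stage_concentration_mean(cfg, s)
    vnuc <- vtot / s
    for (i in seq_len(cfg$n_cells)) {
      conc <- cmean * lognormal_noise(s, cfg$intensity_noise_cv)
      intens <- conc * vnuc
      id <- sprintf("s%02d_c%04d", s, i)
      nuclei_list[[length(nuclei_list) + 1L]] <- data.frame(
        cell_id = id, stage = s, nucleus_index = seq_len(s),
        volume = vnuc, concentration = conc, intensity_sum = intens,
        stringsAsFactors = FALSE)
      tot <- sum(intens)
      cf <- cfg$cytoplasm_signal_fraction
      cells_list[[length(cells_list) + 1L]] <- data.frame(
        cell_id = id, stage = s,
        mother_volume = mother_volume,
        total_nuclear_intensity = tot,
        total_intensity_in_cell = tot / (1 - cf),
        nuclear_fraction = 1 - cf,
        per_dna_ratio = tot / s,
        mean_nucleus_concentration = mean(conc),
        stringsAsFactors = FALSE)
    }
  }
  truth <- data.frame(
    stage = cfg$stage_list,
    true_concentration_mean =
      stage_concentration_mean(cfg, cfg$stage_list),
    true_per_dna_mean =
      stage_concentration_mean(cfg, cfg$stage_list) * vtot /
        cfg$stage_list)
  list(cells = do.call(rbind, cells_list),
       nuclei = do.call(rbind, nuclei_list), truth = truth)
}

#' Render a two-channel image of one multinucleate cell
#'
#' Nuclei are drawn as filled disks of the stage radius on a jittered
#' grid (guaranteeing no overlap and full containment).  The DAPI
#' channel is constant inside nuclei; in the tagged-protein channel each
#' nucleus's per-pixel value is chosen so that the disk sum equals the
#' record's `intensity_sum`, the configured cytoplasmic signal fraction
#' is spread uniformly over the non-nuclear pixels, and a constant
#' background is added everywhere.  Optional additive Gaussian pixel
#' noise is scaled to the nuclear per-pixel amplitude.  The ground-truth
#' label image is returned alongside.
#'
#' @param cell_nuclei Per-nucleus table for one cell (rows of the
#'   `nuclei` element of [gen_if_records()]).
#' @param cfg A [synthetic_config()].
#' @param seed Seed for jitter and pixel noise (default `cfg$seed`).
#' @return A list with matrices `dapi`, `ha`, `labels`, and the scalar
#'   `background`.
#' @export
render_cell_image <- function(cell_nuclei, cfg = synthetic_config(),
                              seed = cfg$seed) {
  stopifnot(is.data.frame(cell_nuclei), nrow(cell_nuclei) >= 1)
  set.seed(seed)
  s <- nrow(cell_nuclei)
  r_um <- stage_nucleus_radius(cfg, s)
  r_px <- max(3L, as.integer(round(r_um / cfg$image_pixel_size)))
  g <- ceiling(sqrt(s))
  cellpx <- 2L * r_px + 8L
  side <- g * cellpx + 4L
  dapi <- matrix(0, side, side)
  ha <- matrix(0, side, side)
  labels <- matrix(0L, side, side)
  jitter_max <- 2L
  rows <- matrix(rep(seq_len(side), side), side, side)
  cols <- matrix(rep(seq_len(side), each = side), side, side)
  for (k in seq_len(s)) {
    gi <- (k - 1L) %/% g
    gj <- (k - 1L) %% g
    cy <- 2L + gi * cellpx + cellpx / 2 +
      sample(-jitter_max:jitter_max, 1)
    cx <- 2L + gj * cellpx + cellpx / 2 +
      sample(-jitter_max:jitter_max, 1)
    disk <- (rows - cy)^2 + (cols - cx)^2 <= r_px^2
    stopifnot(all(labels[disk] == 0L))   # non-overlap by construction
    labels[disk] <- k
    dapi[disk] <- 1
    ha[disk] <- cell_nuclei$intensity_sum[k] / sum(disk)
  }
  cyto <- labels == 0L
  cf <- cfg$cytoplasm_signal_fraction
  if (cf > 0) {
    cyt_total <- sum(cell_nuclei$intensity_sum) * cf / (1 - cf)
    ha[cyto] <- cyt_total / sum(cyto)
  }
  ha <- ha + cfg$background
  if (cfg$pixel_noise_cv > 0) {
    amp <- mean(cell_nuclei$intensity_sum /
                  tabulate(labels[labels > 0], nbins = s))
    ha <- ha + stats::rnorm(length(ha), 0, cfg$pixel_noise_cv * amp)
  }
  list(dapi = dapi, ha = ha, labels = labels,
       background = cfg$background)
}

#' Generate nuclear-marker geometry records across division stages
#'
#' Emulates live imaging of dividing cells expressing a nuclear
#' fluorescent marker: at each stage the representative nuclear diameter
#' follows from the constant total nuclear volume (per-nucleus volume
#' halves per round), cell axes follow from the constant true N/C ratio
#' with a fixed 1.3 aspect ratio, and multiplicative measurement noise
#' is applied to the diameter and both axes.  Group sizes default to 24
#' per stage except 11 at the 16-nucleus stage.
#'
#' @param cfg A [synthetic_config()].
#' @param n_per_stage Optional vector of group sizes matching
#'   `cfg$stage_list`.
#' @return Data frame with per-cell columns `cell_id`, `stage`,
#'   `nucleus_diameter`, `major_axis`, `minor_axis`, plus derived
#'   `nuclear_volume` (per nucleus), `total_nuclear_volume`,
#'   `cell_volume` and `nc`.
#' @export
gen_ble_gfp_geometry <- function(cfg = synthetic_config(),
                                 n_per_stage = NULL) {
  set.seed(cfg$seed + 2L)
  if (is.null(n_per_stage)) {
    n_per_stage <- ifelse(cfg$stage_list >= 16, 11L, 24L)
  }
  stopifnot(length(n_per_stage) == length(cfg$stage_list))
  aspect <- 1.3
  m_vol <- cfg$total_nuclear_volume / cfg$nc_true
  b0 <- aspect * (6 * m_vol / (pi * aspect))^(1 / 3)  # major axis
  rows <- list()
  for (j in seq_along(cfg$stage_list)) {
    s <- cfg$stage_list[j]
    n <- n_per_stage[j]
    d0 <- (6 * (cfg$total_nuclear_volume / s) / pi)^(1 / 3)
    d <- d0 * lognormal_noise(n, cfg$geometry_noise_cv)
    a <- b0 * lognormal_noise(n, cfg$geometry_noise_cv)
    b <- (b0 / aspect) * lognormal_noise(n, cfg$geometry_noise_cv)
    b <- pmin(b, a)   # preserve axis order under noise
    nv <- nuclear_volume_from_diameter(d)
    cv <- cell_volume_ellipsoid(a, b)
    rows[[j]] <- data.frame(
      cell_id = sprintf("g%02d_c%03d", s, seq_len(n)), stage = s,
      nucleus_diameter = d, major_axis = a, minor_axis = b,
      nuclear_volume = nv, total_nuclear_volume = s * nv,
      cell_volume = cv, nc = nc_ratio(s * nv, cv),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
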