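## Quantitative immunofluorescence: nuclear segmentation on the DAPI
## channel, per-nucleus intensity and concentration on the tagged-protein
## channel, stage grouping and the statistics reported for dividing
## cells.  Images are plain numeric matrices, pixel (1,1) top-left,
## row-major display; areas are converted with pixel_size^2.

# 8-connected component labelling of a logical mask.  EBImage::bwlabel is
# 4-connected, so adjacency (including diagonals) is built explicitly and
# components are taken from the pixel adjacency graph.  Labels are
# renumbered 1..K in order of each component's first pixel (column-major).
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    edges[[length(edges) + 1L]] <-
      cbind(id[fg][ok][keep], nb[keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0) {
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  # renumber by first occurrence in pixel order
  first <- match(unique(comp), comp)
  renum <- match(comp, comp[sort.int(first)])
  lab[fg] <- renum
  lab
}

#' Segment nuclei in a DAPI image
#'
#' Global automatic (Otsu) thresholding of the DAPI channel followed by
#' 8-connected component labelling; components with area below
#' `min_area` are discarded.  An all-zero image yields zero nuclei; a
#' constant non-zero (saturated) image is a threshold failure.
#'
#' @param dapi Numeric matrix of DAPI intensities (a maximum projection
#'   for z-stacks, see [max_projection()]).
#' @param pixel_size Pixel edge length in micrometres.
#' @param min_area Minimum nuclear area in square micrometres.
#' @return A list with `labels` (integer label matrix, 0 = background),
#'   `areas` (named vector of areas in um^2 per label) and `threshold`.
#' @export
segment_nuclei <- function(dapi, pixel_size, min_area = 0) {
  stopifnot(is.matrix(dapi), length(dapi) > 0)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("'pixel_size' must be positive", call. = FALSE)
  }
  rng <- range(dapi)
  if (diff(rng) == 0) {
    if (rng[1] == 0) {
      return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                  areas = numeric(0), threshold = NA_real_))
    }
    stop("threshold failure: constant (saturated) image", call. = FALSE)
  }
  th <- EBImage::otsu(dapi, range = rng, levels = 256)
  lab <- label_components8(dapi > th)
  if (max(lab) > 0) {
    px <- tabulate(lab[lab > 0])
    areas <- px * pixel_size^2
    keep <- which(areas >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
    areas <- areas[keep]
  } else {
    areas <- numeric(0)
  }
  if (length(areas)) names(areas) <- seq_along(areas)
  list(labels = lab, areas = areas, threshold = th)
}

#' Maximum projection of an image stack
#'
#' @param stack A 3-d numeric array (rows x cols x slices) or a matrix
#'   (returned unchanged).
#' @return A matrix of per-pixel maxima across slices.
#' @export
max_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  apply(stack, c(1, 2), max)
}

#' Measure per-nucleus intensity and concentration
#'
#' For each segmented nucleus, sums the background-subtracted tagged
#' protein signal over the nucleus pixels (each pixel's excess over
#' background, floored at zero), converts the projected area to a
#' nuclear volume, and reports the nuclear concentration as summed
#' intensity over volume.  Background is a scalar per image, estimated
#' from an untagged control.
#'
#' @param ha Numeric matrix of the tagged-protein channel, congruent
#'   with the label image.
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param pixel_size Pixel edge length in micrometres.
#' @param background Scalar background level (AU per pixel).
#' @param corrected Passed to [nuclear_volume_from_area()].
#' @return Data frame with columns `nucleus_id`, `projected_area`,
#'   `volume`, `intensity_sum`, `concentration`.
#' @export
measure_nuclei <- function(ha, labels, pixel_size, background = 0,
                           corrected = FALSE) {
  if (!is.matrix(ha) || !identical(dim(ha), dim(labels))) {
    stop("'ha' and 'labels' must be matrices of identical shape",
         call. = FALSE)
  }
  k <- max(labels)
  if (k == 0) {
    return(data.frame(nucleus_id = integer(), projected_area = numeric(),
                      volume = numeric(), intensity_sum = numeric(),
                      concentration = numeric()))
  }
  excess <- pmax(ha - background, 0)
  inside <- labels > 0
  sums <- as.numeric(tapply(excess[inside], labels[inside], sum))
  px <- tabulate(labels[inside], nbins = k)
  areas <- px * pixel_size^2
  vols <- nuclear_volume_from_area(areas, corrected = corrected)
  data.frame(nucleus_id = seq_len(k), projected_area = areas,
             volume = vols, intensity_sum = sums,
             concentration = sums / vols)
}

#' Quantify one (possibly multinucleate) cell image
#'
#' Runs segmentation and per-nucleus measurement and assembles the
#' per-cell record: division stage (number of nuclei), total
#' background-subtracted signal in the cell, fraction of signal within
#' nuclei, and the per-DNA ratio (summed nuclear intensity over nuclei
#' count, one genome copy per nucleus).
#'
#' @param dapi,ha Congruent matrices for the DAPI and tagged-protein
#'   channels.
#' @param pixel_size Pixel edge length in micrometres.
#' @param background Scalar background (AU per pixel).
#' @param min_area Minimum nuclear area passed to [segment_nuclei()].
#' @param cell_mask Optional logical matrix marking the cell; defaults to
#'   the whole frame.
#' @param corrected Passed to [nuclear_volume_from_area()].
#' @param cell_id Identifier stored in the record.
#' @return A list with `nuclei` (the [measure_nuclei()] table) and
#'   `cell`, a one-row data frame with columns `cell_id`, `stage`,
#'   `total_nuclear_intensity`, `total_intensity_in_cell`,
#'   `nuclear_fraction`, `per_dna_ratio`, `mean_nucleus_concentration`.
#' @export
quantify_cell_image <- function(dapi, ha, pixel_size, background = 0,
                                min_area = 0, cell_mask = NULL,
                                corrected = FALSE, cell_id = "cell1") {
  if (!identical(dim(dapi), dim(ha))) {
    stop("channel images differ in shape", call. = FALSE)
  }
  seg <- segment_nuclei(dapi, pixel_size, min_area)
  nuc <- measure_nuclei(ha, seg$labels, pixel_size, background, corrected)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(ha), ncol(ha))
  total <- sum(pmax(ha[cell_mask] - background, 0))
  nuc_total <- sum(nuc$intensity_sum)
  stage <- nrow(nuc)
  cell <- data.frame(
    cell_id = cell_id, stage = stage,
    total_nuclear_intensity = nuc_total,
    total_intensity_in_cell = total,
    nuclear_fraction = if (total > 0) nuc_total / total else NA_real_,
    per_dna_ratio = if (stage > 0) nuc_total / stage else NA_real_,
    mean_nucleus_concentration = if (stage > 0) mean(nuc$concentration)
                                 else NA_real_,
    stringsAsFactors = FALSE)
  list(nuclei = nuc, cell = cell)
}

# inclusion filter: cells from mothers predicted by size to complete at
# least `min_rounds` divisions
filter_by_predicted_rounds <- function(cells, params, min_rounds = 3) {
  if (is.null(params) || !"mother_volume" %in% names(cells)) return(cells)
  pred <- predict_n_rounds(cells$mother_volume, params$exit_threshold,
                           params$degradation_fraction,
                           params$production_exponent, params)
  cells[pred >= min_rounds, , drop = FALSE]
}

#' Per-stage summaries of nuclear concentration
#'
#' Groups cell records by division stage (nuclei count) and reports the
#' mean and SD of the per-cell mean nuclear concentration.  When model
#' parameters and mother volumes are available, only cells from mothers
#' predicted by size to complete at least three divisions are included,
#' so that concentrations at different stages are comparable.  Stages
#' with fewer than `min_cells_per_stage` cells are flagged.
#'
#' @param cells Data frame of per-cell records with columns `stage` and
#'   `mean_nucleus_concentration` (and optionally `mother_volume`).
#' @param min_cells_per_stage Minimum group size before a stage is
#'   flagged (default 68).
#' @param params Optional [model_params()] for the size-based inclusion
#'   filter.
#' @param min_predicted_rounds Inclusion filter cut-off (default 3).
#' @return Data frame with columns `stage`, `n`, `mean`, `sd`,
#'   `flagged`.
#' @export
stage_summaries <- function(cells, min_cells_per_stage = 68,
                            params = NULL, min_predicted_rounds = 3) {
  stopifnot(is.data.frame(cells),
            all(c("stage", "mean_nucleus_concentration") %in% names(cells)))
  cells <- filter_by_predicted_rounds(cells, params, min_predicted_rounds)
  stages <- sort(unique(cells$stage))
  out <- do.call(rbind, lapply(stages, function(s) {
    x <- cells$mean_nucleus_concentration[cells$stage == s]
    data.frame(stage = s, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0)
  }))
  out$flagged <- out$n < min_cells_per_stage
  if (all(out$flagged)) {
    stop("no stage reaches min_cells_per_stage = ", min_cells_per_stage,
         call. = FALSE)
  }
  out
}

#' Normalised per-stage per-DNA ratio series
#'
#' Per-stage mean of the per-DNA ratio (total nuclear signal over genome
#' copies), normalised so the first stage equals 1 arbitrary unit.
#'
#' @param cells Data frame with columns `stage` and `per_dna_ratio`.
#' @return Data frame with columns `stage`, `mean_per_dna`,
#'   `normalized`.
#' @export
per_dna_series <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("stage", "per_dna_ratio") %in% names(cells)))
  stages <- sort(unique(cells$stage))
  if (length(stages) < 2) {
    stop("at least two stages are required", call. = FALSE)
  }
  m <- vapply(stages,
              function(s) mean(cells$per_dna_ratio[cells$stage == s]),
              numeric(1))
  if (m[1] == 0) stop("first-stage mean is zero; cannot normalise",
                      call. = FALSE)
  data.frame(stage = stages, mean_per_dna = m, normalized = m / m[1])
}

#' Ordinary least squares on ordered stage means
#'
#' Fits mean concentration against stage index (1, 2, ...) and reports
#' the slope, intercept and coefficient of determination.
#'
#' @param stage_means Numeric vector of stage means in stage order
#'   (length >= 3).
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_means <- function(stage_means) {
  if (!is.numeric(stage_means) || length(stage_means) < 3) {
    stop("at least three stage means are required", call. = FALSE)
  }
  x <- seq_along(stage_means)
  fit <- stats::lm(stage_means ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((stage_means - mean(stage_means))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Two-sided rank-sum comparison of two stage groups
#'
#' Mann-Whitney rank-sum test, the conventional reading of a
#' "non-parametric t test": exact enumeration for small tie-free groups
#' (both sizes at most 20), otherwise the normal approximation with tie
#' correction (and no continuity correction, so identical groups give
#' p = 1).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @return A list with `statistic` (the Mann-Whitney U for `group_a`),
#'   `p_value` and `method`.
#' @export
compare_stages <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) <= 20 && length(group_b) <= 20
  ht <- stats::wilcox.test(group_a, group_b, exact = exact,
                           correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' One-way ANOVA across stage groups of N/C ratios
#'
#' Standard one-way analysis of variance of per-cell N/C values grouped
#' by nuclei count.  Degenerate input in which every group is the same
#' constant returns `F = 0`, `p = 1` by convention.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return A list with `statistic` (F), `p_value`, `df_between`,
#'   `df_within`.
#' @export
nc_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  dfb <- length(groups) - 1L
  dfw <- length(value) - length(groups)
  gm <- vapply(split(value, grp), mean, numeric(1))
  ssw <- sum((value - gm[grp])^2)
  ssb <- sum(tabulate(grp) * (gm - mean(value))^2)
  if (ssw == 0 && ssb == 0) {
    return(list(statistic = 0, p_value = 1, df_between = dfb,
                df_within = dfw))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(statistic = f,
       p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

#' Fraction of cells with predominantly nuclear signal, by stage
#'
#' Per stage, the proportion of cells whose nuclear signal fraction
#' strictly exceeds one half; cells with zero total signal are excluded
#' (their count is reported via a message and an attribute).
#'
#' @param cells Data frame with columns `stage`, `nuclear_fraction`,
#'   `total_intensity_in_cell`.
#' @return Data frame with columns `stage`, `n`, `fraction_above_half`;
#'   attribute `n_excluded` carries the number of zero-signal cells.
#' @export
nuclear_fraction_score <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("stage", "nuclear_fraction",
                  "total_intensity_in_cell") %in% names(cells)))
  excl <- cells$total_intensity_in_cell <= 0
  if (any(excl)) {
    message(sum(excl), " cell(s) with zero total signal excluded")
  }
  cells <- cells[!excl, , drop = FALSE]
  stages <- sort(unique(cells$stage))
  out <- do.call(rbind, lapply(stages, function(s) {
    x <- cells$nuclear_fraction[cells$stage == s]
    data.frame(stage = s, n = length(x),
               fraction_above_half = mean(x > 0.5))
  }))
  attr(out, "n_excluded") <- sum(excl)
  out
}
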