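#' Configuration for the synthetic FPKM time-series generator
#'
#' Describes a simulated bulk RNA-seq experiment: several cultures profiled at
#' successive passages, a stable housekeeping gene, and a planted fraction of
#' features with constant log2 up- or down-regulation per time step.
#'
#' @param n_features Number of non-housekeeping features to simulate.
#' @param n_cultures Number of independent cultures.
#' @param n_timepoints Number of profiled passages (>= 2).
#' @param frac_up,frac_down Fractions of features with a planted monotone
#'   trend; `frac_up + frac_down` must not exceed 1.
#' @param fold_per_step Expected fold change per time step for trending
#'   features (> 1); "down" features change by `1 / fold_per_step` per step.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noiseless).
#' @param housekeeping_id Label of the constant housekeeping feature appended
#'   to the matrix.
#' @param baseline_fpkm_range Positive interval from which per-feature baseline
#'   FPKM values are drawn (log-uniformly, FPKM being right-skewed). The
#'   default keeps planted trend features expressed above the pipeline's
#'   low-expression thresholds, so trend-recovery tests probe the classifier
#'   rather than the filter.
#' @param seed Integer RNG seed; identical configurations yield identical data.
#'
#' @return A validated list of class `fpkm_sim_config`.
#' @export
fpkm_sim_config <- function(n_features = 1000L, n_cultures = 4L,
                            n_timepoints = 3L, frac_up = 0.1, frac_down = 0.1,
                            fold_per_step = 2, noise_cv = 0.1,
                            housekeeping_id = "GAPDH",
                            baseline_fpkm_range = c(5, 100), seed = 1L) {
  n_features <- assert_count(n_features, "n_features", lower = 1L)
  n_cultures <- assert_count(n_cultures, "n_cultures", lower = 1L)
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", lower = 2L)
  assert_proportion(frac_up, "frac_up")
  assert_proportion(frac_down, "frac_down")
  if (frac_up + frac_down > 1) abort_input("frac_up + frac_down must be <= 1")
  assert_scalar_number(fold_per_step, "fold_per_step", lower = 1,
                       strict_lower = TRUE)
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  if (!is.character(housekeeping_id) || length(housekeeping_id) != 1L) {
    abort_input("housekeeping_id must be a single string")
  }
  if (length(baseline_fpkm_range) != 2L || any(baseline_fpkm_range <= 0) ||
      diff(baseline_fpkm_range) < 0) {
    abort_input("baseline_fpkm_range must be a positive increasing interval")
  }
  structure(list(n_features = n_features, n_cultures = n_cultures,
                 n_timepoints = n_timepoints, frac_up = frac_up,
                 frac_down = frac_down, fold_per_step = fold_per_step,
                 noise_cv = noise_cv, housekeeping_id = housekeeping_id,
                 baseline_fpkm_range = as.numeric(baseline_fpkm_range),
                 seed = assert_count(seed, "seed")),
            class = "fpkm_sim_config")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Generate a synthetic FPKM expression matrix with planted trends
#'
#' Features are assigned directions deterministically: the first
#' `round(frac_up * n_features)` are "up", the next `round(frac_down *
#' n_features)` are "down", the remainder flat. Expected expression of an "up"
#' feature at time t (0-based) is `baseline * fold_per_step^t`, of a "down"
#' feature `baseline * fold_per_step^(-t)`; flat features and the housekeeping
#' gene stay at their baseline. Multiplicative lognormal noise with mean 1 and
#' coefficient of variation `noise_cv` is applied to every measurement.
#'
#' @param config An [fpkm_sim_config()].
#' @return A list with `matrix` (a wide expression data frame: `feature_id`,
#'   `feature_kind`, `culture_id`, `status`, `t0`..`tK`) and `truth` (a data
#'   frame of per-feature planted `direction` and `baseline`).
#' @export
gen_fpkm_dataset <- function(config) {
  if (!inherits(config, "fpkm_sim_config")) {
    abort_input("config must be created by fpkm_sim_config()")
  }
  with_seed(config$seed, {
    n <- config$n_features
    n_up <- round(config$frac_up * n)
    n_down <- round(config$frac_down * n)
    direction <- rep(c("up", "down", "flat"), c(n_up, n_down, n - n_up - n_down))
    ids <- sprintf("G%05d", seq_len(n))
    lo <- log(config$baseline_fpkm_range[1])
    hi <- log(config$baseline_fpkm_range[2])
    baseline <- exp(stats::runif(n, lo, hi))
    hk_baseline <- exp((lo + hi) / 2)

    tt <- seq_len(config$n_timepoints) - 1L
    step_log <- log(config$fold_per_step) *
      ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
    # expected values: features x timepoints
    expected <- exp(outer(log(baseline), rep(1, length(tt))) +
                      outer(step_log, tt))
    expected <- rbind(expected, rep(hk_baseline, length(tt)))

    cultures <- sprintf("C%d", seq_len(config$n_cultures))
    blocks <- lapply(cultures, function(cid) {
      noise <- matrix(rlnorm_cv1(length(expected), config$noise_cv),
                      nrow = nrow(expected))
      vals <- expected * noise
      colnames(vals) <- sprintf("t%d", tt)
      data.frame(feature_id = c(ids, config$housekeeping_id),
                 feature_kind = "gene", culture_id = cid, status = "ok",
                 vals, stringsAsFactors = FALSE, check.names = FALSE)
    })
    mat <- do.call(rbind, blocks)
    rownames(mat) <- NULL
    truth <- data.frame(feature_id = ids, direction = direction,
                        baseline = baseline, stringsAsFactors = FALSE)
    list(matrix = mat, truth = truth)
  })
}

#' Generate a synthetic serial-passage colony assay series
#'
#' Emulates a culture propagated until replicative exhaustion. Expected colony
#' forming efficiency decays exponentially, `cfe0 * exp(-decay * (p - 1))`,
#' and is forced to 0 at the planted exhaustion passage `p_star`. Planted
#' per-passage population doublings decline linearly from `doublings0` at the
#' first passage to 0 at exhaustion (senescing cultures expand less each
#' passage); the cell yield is derived from them. The aborted-colony fraction
#' ramps linearly from 0 to 1 at exhaustion.
#'
#' @param p_star Planted exhaustion passage (>= 1).
#' @param cfe0 Initial colony forming efficiency in (0, 1].
#' @param decay Exponential CFE decay rate per passage (>= 0).
#' @param inoculum Cells plated at every passage (> 0).
#' @param doublings0 Expected population doublings at the first passage.
#' @param noise_cv Multiplicative lognormal noise on CFE and yield (0 = none).
#' @param culture_id Label carried on every record.
#' @param seed Integer RNG seed.
#' @return A list with `records` (a passage-record data frame: `culture_id`,
#'   `passage`, `inoculum`, `cfe`, `cell_yield`, `aborted_fraction`) and
#'   `truth` (exhaustion passage, planted per-passage doublings, expected CFE).
#' @export
gen_colony_series <- function(p_star, cfe0 = 0.1, decay = 0.2,
                              inoculum = 10000, doublings0 = 6,
                              noise_cv = 0, culture_id = "C1", seed = 1L) {
  p_star <- assert_count(p_star, "p_star", lower = 1L)
  assert_scalar_number(cfe0, "cfe0", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(decay, "decay", lower = 0)
  assert_scalar_number(inoculum, "inoculum", lower = 0, strict_lower = TRUE)
  assert_scalar_number(doublings0, "doublings0", lower = 0)
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  with_seed(seed, {
    p <- seq_len(p_star)
    expected_cfe <- cfe0 * exp(-decay * (p - 1))
    expected_cfe[p_star] <- 0
    planted_pd <- if (p_star == 1L) {
      0
    } else {
      doublings0 * (p_star - p) / (p_star - 1)
    }
    cfe <- pmin(expected_cfe * rlnorm_cv1(p_star, noise_cv), 1)
    cfe[p_star] <- 0
    clonogenic <- inoculum * cfe
    cell_yield <- clonogenic * 2^planted_pd * rlnorm_cv1(p_star, noise_cv)
    cell_yield[cfe == 0] <- 0
    aborted <- if (p_star == 1L) 1 else pmin(1, (p - 1) / (p_star - 1))
    records <- data.frame(culture_id = culture_id, passage = p,
                          inoculum = inoculum, cfe = cfe,
                          cell_yield = cell_yield,
                          aborted_fraction = aborted,
                          stringsAsFactors = FALSE)
    list(records = records,
         truth = list(exhaustion_passage = p_star,
                      planted_doublings = planted_pd,
                      expected_cfe = expected_cfe))
  })
}

# uniform integer in [a, b]; safe for a == b (unlike sample(a:b, 1))
sample_range <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# Pixel coordinates (0-based, row-major) of a block of exactly `area` pixels
# anchored at (row0, col0): a w x h rectangle with the surplus of the last row
# trimmed, so planted spot areas are exact.
block_pixels <- function(row0, col0, area) {
  w <- max(1L, floor(sqrt(area)))
  h <- ceiling(area / w)
  rows <- rep(row0 + seq_len(h) - 1L, each = w)
  cols <- rep(col0 + seq_len(w) - 1L, times = h)
  cbind(row = rows[seq_len(area)], col = cols[seq_len(area)])
}

#' Generate a synthetic Q-FISH image with planted telomeric spots
#'
#' Draws `cells` rectangular cell ROIs on a constant background and places
#' non-overlapping constant-intensity spots (axis-aligned pixel blocks of
#' exact area) inside each. The planted per-cell relative telomere length is
#' the sum over spots of mean intensity times area. Spots are separated by at
#' least one background pixel so they remain distinct 8-connected components.
#'
#' @param cells Number of cells (laid out on a grid).
#' @param spots_per_cell Integer range `c(min, max)` of spots per cell.
#' @param spot_area Integer range of spot areas in pixels.
#' @param spot_intensity Range of spot intensities (arbitrary 16-bit units);
#'   must exceed `background`.
#' @param background Constant background level.
#' @param size Image size `c(rows, cols)`.
#' @param noise_sd Additive Gaussian noise standard deviation (0 = noiseless);
#'   values are clipped to the 16-bit range.
#' @param max_retries Placement retries per spot before giving up.
#' @param seed Integer RNG seed.
#' @return A list with `image` (integer matrix), `rois` (list of cell ROIs,
#'   each `list(cell_id, rect = c(row0, col0, row1, col1))`, half-open,
#'   0-based), and `truth` (per-cell planted RTL and a spot table).
#' @export
gen_fish_image <- function(cells = 4L, spots_per_cell = c(3L, 8L),
                           spot_area = c(4L, 16L),
                           spot_intensity = c(5000, 20000),
                           background = 500, size = c(128L, 128L),
                           noise_sd = 0, max_retries = 200L, seed = 1L) {
  cells <- assert_count(cells, "cells", lower = 1L)
  assert_scalar_number(background, "background", lower = 0)
  if (min(spot_intensity) <= background) {
    abort_input("spot intensity must exceed background")
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    ncol_grid <- ceiling(sqrt(cells))
    nrow_grid <- ceiling(cells / ncol_grid)
    cell_h <- nr %/% nrow_grid
    cell_w <- nc %/% ncol_grid
    occupied <- matrix(FALSE, nr, nc)  # spot pixels incl. 1-px halo
    img <- matrix(background, nr, nc)
    rois <- vector("list", cells)
    spot_rows <- list()
    rtl <- numeric(cells)
    for (ci in seq_len(cells)) {
      gr <- (ci - 1L) %/% ncol_grid
      gc <- (ci - 1L) %% ncol_grid
      margin <- 2L
      r0 <- gr * cell_h + margin; r1 <- (gr + 1L) * cell_h - margin
      c0 <- gc * cell_w + margin; c1 <- (gc + 1L) * cell_w - margin
      cell_id <- sprintf("cell%02d", ci)
      rois[[ci]] <- list(cell_id = cell_id, rect = c(r0, c0, r1, c1))
      n_spots <- sample_range(spots_per_cell[1], spots_per_cell[2])
      for (si in seq_len(n_spots)) {
        area <- sample_range(spot_area[1], spot_area[2])
        intensity <- round(stats::runif(1, spot_intensity[1], spot_intensity[2]))
        w <- max(1L, floor(sqrt(area))); h <- ceiling(area / w)
        if (r0 + h > r1 || c0 + w > c1) {
          abort_input("spot of area ", area, " does not fit cell ROI")
        }
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          pr <- sample_range(r0, r1 - h)
          pc <- sample_range(c0, c1 - w)
          px <- block_pixels(pr, pc, area)
          # 1-px halo keeps spots 8-disconnected from each other
          halo_r <- pmax(1L, pmin(nr, rep(px[, 1] + 1L, 9) +
                                    rep(-1:1, each = 3 * nrow(px))))
          halo_c <- pmax(1L, pmin(nc, rep(px[, 2] + 1L, 9) +
                                    rep(rep(-1:1, each = nrow(px)), 3)))
          if (!any(occupied[cbind(halo_r, halo_c)])) {
            occupied[cbind(halo_r, halo_c)] <- TRUE
            img[px + 1L] <- intensity
            spot_rows[[length(spot_rows) + 1L]] <-
              data.frame(cell_id = cell_id, area = area,
                         intensity = intensity, stringsAsFactors = FALSE)
            rtl[ci] <- rtl[ci] + intensity * area
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort_input("could not place spot without overlap after ",
                      max_retries, " retries")
        }
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nr, nc)
    }
    img <- matrix(as.integer(pmin(65535, pmax(0, round(img)))), nr, nc)
    truth <- list(
      rtl = data.frame(cell_id = vapply(rois, `[[`, "", "cell_id"),
                       rtl = rtl, stringsAsFactors = FALSE),
      spots = do.call(rbind, spot_rows))
    list(image = img, rois = rois, truth = truth)
  })
}

#' Generate a synthetic diffuse-staining image for CTCF quantification
#'
#' A single cell region of exactly `cell_area` pixels at mean level
#' `cell_mean` on a uniform background at `background_mean`. The planted
#' corrected total cell fluorescence is
#' `cell_area * (cell_mean - background_mean)` in the noiseless case.
#'
#' @param cell_mean,background_mean Mean pixel levels; `cell_mean` must be at
#'   least `background_mean`, both non-negative.
#' @param cell_area Cell region area in pixels.
#' @param size Image size `c(rows, cols)`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @return A list with `image`, `cell_roi` (pixel-list ROI), `background_roi`
#'   (rect ROI away from the cell), and `truth` (planted CTCF).
#' @export
gen_diffuse_image <- function(cell_mean = 10000, cell_area = 100,
                              background_mean = 2000, size = c(64L, 64L),
                              noise_sd = 0, seed = 1L) {
  assert_scalar_number(background_mean, "background_mean", lower = 0)
  assert_scalar_number(cell_mean, "cell_mean", lower = background_mean)
  cell_area <- assert_count(cell_area, "cell_area", lower = 1L)
  nr <- size[1]; nc <- size[2]
  w <- max(1L, floor(sqrt(cell_area))); h <- ceiling(cell_area / w)
  if (h + 2 > nr || w + 2 > nc %/% 2) {
    abort_input("cell ROI of area ", cell_area, " does not fit the image")
  }
  with_seed(seed, {
    img <- matrix(background_mean, nr, nc)
    px <- block_pixels(2L, 2L, cell_area)
    img[px + 1L] <- cell_mean
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nr, nc)
    }
    img <- matrix(as.integer(pmin(65535, pmax(0, round(img)))), nr, nc)
    cell_roi <- list(cell_id = "cell01",
                     pixels = unname(as.matrix(px)))
    bg_roi <- list(cell_id = "background",
                   rect = c(2L, nc %/% 2 + 2L, nr - 2L, nc - 2L))
    list(image = img, cell_roi = cell_roi, background_roi = bg_roi,
         truth = list(ctcf = cell_area * (cell_mean - background_mean)))
  })
}
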