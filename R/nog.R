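#' Fluorescence intensity profile on the 0.1 um grid
#'
#' Container for a resampled line-scan profile: a uniform distance grid in
#' 0.1 um steps (distance 0 at the microgroove wall edge; cell-body
#' distances increase leftward, neurite distances rightward) and one mean
#' gray value per grid point.
#'
#' @param distance numeric grid (multiples of 0.1 um, strictly
#'   increasing).
#' @param intensity non-negative intensities, one per grid point.
#' @param side `"cell_body"` or `"neurite"`.
#' @param chamber_id,experiment_id,condition,gene optional identifiers.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(distance, intensity, side = "neurite",
                              chamber_id = NA_character_,
                              experiment_id = NA_character_,
                              condition = NA_character_,
                              gene = NA_character_) {
  stopifnot(length(distance) == length(intensity))
  side <- match.arg(side, c("neurite", "cell_body"))
  steps <- round(diff(distance), 6)
  if (length(steps) > 0 && any(abs(steps - 0.1) > 1e-6)) {
    stop("profile grid must be uniform at 0.1 um", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(distance = distance, intensity = intensity, side = side,
         chamber_id = chamber_id, experiment_id = experiment_id,
         condition = condition, gene = gene),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %s side, %.1f-%.1f um (%d points)\n",
              x$side, min(x$distance), max(x$distance), length(x$distance)))
  invisible(x)
}

# snap to the 0.1-um lattice, robust to floating point drift
grid_points <- function(from, to) {
  round(seq(ceiling(round(from * 10, 6)), floor(round(to * 10, 6)))) / 10
}

#' Resample a raw line scan onto the 0.1 um grid
#'
#' Linearly interpolates measured (distance, intensity) pairs onto the
#' 0.1 um lattice covering the measured range, assuming a linear increase
#' or decrease between adjacent measurements.  No extrapolation beyond
#' the first and last raw point.
#'
#' @param raw two-column data frame or matrix (distance in um, mean gray
#'   value) with at least two rows and strictly increasing distances.
#' @inheritParams intensity_profile
#' @return An [intensity_profile()].
#' @export
resample_profile <- function(raw, side = "neurite",
                             chamber_id = NA_character_,
                             experiment_id = NA_character_,
                             condition = NA_character_,
                             gene = NA_character_) {
  raw <- as.data.frame(raw)
  if (nrow(raw) < 2) stop("need at least two measured points", call. = FALSE)
  d <- as.numeric(raw[[1]])
  v <- as.numeric(raw[[2]])
  if (any(diff(d) <= 0)) {
    stop("distances must be strictly increasing", call. = FALSE)
  }
  grid <- grid_points(min(d), max(d))
  out <- stats::approx(d, v, xout = grid, method = "linear")$y
  intensity_profile(grid, out, side = side, chamber_id = chamber_id,
                    experiment_id = experiment_id, condition = condition,
                    gene = gene)
}

#' Merge overlapping image profiles of one chamber
#'
#' Microchambers are often documented by several overlapping images.
#' Each image profile is shifted by its stated offset onto the common
#' chamber axis, and the merged profile takes, at every grid point, the
#' mean over the images covering that point -- so overlapping stretches
#' are counted once per image, never double-counted within one image.
#' A gap in the combined coverage is an error.
#'
#' @param profiles list of [intensity_profile()]s sharing side and
#'   chamber.
#' @param offsets numeric vector of per-image offsets (um, multiples of
#'   0.1) added to each profile's distances; defaults to all zero.
#' @return A single merged [intensity_profile()].
#' @export
merge_image_profiles <- function(profiles, offsets = rep(0, length(profiles))) {
  stopifnot(length(profiles) >= 1, length(offsets) == length(profiles))
  sides <- unique(vapply(profiles, `[[`, character(1), "side"))
  if (length(sides) != 1) {
    stop("profiles to merge must share the same side", call. = FALSE)
  }
  shifted <- Map(function(p, o) {
    list(idx = round((p$distance + o) * 10), val = p$intensity)
  }, profiles, offsets)
  lo <- min(vapply(shifted, function(s) min(s$idx), numeric(1)))
  hi <- max(vapply(shifted, function(s) max(s$idx), numeric(1)))
  n <- hi - lo + 1
  sum_v <- numeric(n)
  cnt <- integer(n)
  for (s in shifted) {
    pos <- s$idx - lo + 1
    sum_v[pos] <- sum_v[pos] + s$val
    cnt[pos] <- cnt[pos] + 1L
  }
  if (any(cnt == 0)) {
    stop("gap in combined image coverage; images do not tile the chamber",
         call. = FALSE)
  }
  p1 <- profiles[[1]]
  intensity_profile(seq(lo, hi) / 10, sum_v / cnt, side = p1$side,
                    chamber_id = p1$chamber_id,
                    experiment_id = p1$experiment_id,
                    condition = p1$condition, gene = p1$gene)
}

#' Highest windowed peak near the wall
#'
#' Intensities are first normalized to percent of the maximum within the
#' first `norm_window` um (100 um by default, i.e. two-thirds of the
#' 150 um microgroove width).  A grid point is a peak iff it is the
#' strict maximum of the `window` um interval centred on it (interval
#' truncated at the profile boundaries; ties yield no peak).  The highest
#' such peak within `search_limit` um of the wall is returned.
#'
#' @param profile an [intensity_profile()].
#' @param search_limit search range from the wall in um, default 50.
#' @param window peak window width in um, default 5.
#' @param norm_window normalization range in um, default 100.
#' @return List `peak_distance`, `peak_normalized_intensity` (percent),
#'   or both `NA` when no strict peak exists (`found = FALSE`).
#' @export
find_highest_peak <- function(profile, search_limit = 50, window = 5,
                              norm_window = 100) {
  d <- profile$distance
  x <- profile$intensity
  if (max(d) - min(d) < window) {
    stop("profile must cover at least the peak window", call. = FALSE)
  }
  in_norm <- d <= min(d) + norm_window + 1e-9
  ref <- max(x[in_norm])
  if (ref <= 0) {
    return(list(found = FALSE, peak_distance = NA_real_,
                peak_normalized_intensity = NA_real_))
  }
  z <- 100 * x / ref
  half <- round(window / 2 / 0.1)         # half window in grid steps
  cand <- which(d <= min(d) + search_limit + 1e-9)
  best_i <- NA_integer_
  for (i in cand) {
    lo <- max(1L, i - half)
    hi <- min(length(z), i + half)
    w <- z[lo:hi]
    if (z[i] > max(w[-(i - lo + 1L)])) {
      if (is.na(best_i) || z[i] > z[best_i]) best_i <- i
    }
  }
  if (is.na(best_i)) {
    return(list(found = FALSE, peak_distance = NA_real_,
                peak_normalized_intensity = NA_real_))
  }
  list(found = TRUE, peak_distance = d[best_i],
       peak_normalized_intensity = z[best_i])
}

#' Cell-body damage quality control
#'
#' After axotomy, an undamaged cell-body side shows its intense line of
#' tubulin staining close to the microgroove wall.  The check normalizes
#' the cell-body profile to the maximum within the first 100 um, finds
#' the highest 5 um-window peak within the first 50 um, and passes iff
#' that peak exists and its normalized intensity is at least
#' `min_peak_pct` percent (85 by default, inclusive).  Profiles covering
#' less than the normalization window are flagged inconclusive for
#' manual review.
#'
#' @param profile a cell-body [intensity_profile()].
#' @param min_peak_pct pass threshold in percent, default 85.
#' @return One of `"pass"`, `"damaged"`, `"inconclusive"`.
#' @export
qc_cell_body <- function(profile, min_peak_pct = 85) {
  if (profile$side != "cell_body") {
    stop("qc_cell_body expects a cell-body profile", call. = FALSE)
  }
  if (max(profile$distance) - min(profile$distance) < 100 - 1e-9) {
    warning("profile covers less than 100 um; QC inconclusive",
            call. = FALSE)
    return("inconclusive")
  }
  pk <- find_highest_peak(profile)
  if (!pk$found || pk$peak_normalized_intensity < min_peak_pct) {
    "damaged"
  } else {
    "pass"
  }
}

#' Normalize profiles of one experiment to the control at 100 um
#'
#' Computes the pointwise mean profile of the experiment's control
#' chambers, then rescales every profile (samples and controls alike) so
#' that the control mean at 100 um equals 100.  The interpolated grid
#' value at exactly 100 um anchors the scale.
#'
#' @param profiles list of neurite-side [intensity_profile()]s.
#' @param controls list of control [intensity_profile()]s covering
#'   100 um.
#' @return List `profiles` (rescaled inputs), `control_mean` (rescaled
#'   mean control profile), `scale` (multiplier applied).
#' @export
normalize_to_control <- function(profiles, controls) {
  stopifnot(length(controls) >= 1)
  idx <- lapply(controls, function(p) round(p$distance * 10))
  lo <- max(vapply(idx, min, numeric(1)))
  hi <- min(vapply(idx, max, numeric(1)))
  if (lo > 1000 || hi < 1000) {
    stop("controls must jointly cover the 100 um anchor", call. = FALSE)
  }
  grid_idx <- seq(lo, hi)
  vals <- vapply(seq_along(controls), function(i) {
    controls[[i]]$intensity[match(grid_idx, idx[[i]])]
  }, numeric(length(grid_idx)))
  mean_v <- if (is.matrix(vals)) rowMeans(vals) else vals
  anchor <- mean_v[match(1000, grid_idx)]
  if (!is.finite(anchor) || anchor <= 0) {
    stop("control mean at 100 um must be positive", call. = FALSE)
  }
  scale <- 100 / anchor
  rescale <- function(p) {
    p$intensity <- p$intensity * scale
    p
  }
  ctrl_mean <- intensity_profile(grid_idx / 10, mean_v * scale,
                                 side = controls[[1]]$side,
                                 experiment_id = controls[[1]]$experiment_id,
                                 condition = "control_mean")
  list(profiles = lapply(profiles, rescale), control_mean = ctrl_mean,
       scale = scale)
}

#' Evaluate a profile at arbitrary distances
#'
#' Linear interpolation between the profile's grid points; `NA` outside
#' its coverage.
#'
#' @param profile an [intensity_profile()].
#' @param at numeric distances (um).
#' @return Numeric vector of intensities.
#' @export
profile_value_at <- function(profile, at) {
  stats::approx(profile$distance, profile$intensity, xout = at,
                method = "linear", rule = 1)$y
}

#' Reference comparison distances from the control decay
#'
#' Outgrowth varies strongly between experiments, so knockdown and
#' control are compared at experiment-specific distances: for each
#' requested level (75, 50, 25 percent of the control intensity at the
#' 100 um anchor) the smallest distance at or beyond 100 um where the
#' normalized control mean first falls to or below that level, with the
#' exact crossing located by linear interpolation between bracketing grid
#' points.  Levels never reached within the control's coverage come back
#' `NA`.
#'
#' @param control_mean normalized control mean profile (value 100 at
#'   100 um).
#' @param levels percent levels, default `c(75, 50, 25)`.
#' @return Named numeric vector of distances (um), names like `"75"`.
#' @export
find_reference_distances <- function(control_mean, levels = c(75, 50, 25)) {
  d <- control_mean$distance
  x <- control_mean$intensity
  sel <- d >= 100 - 1e-9
  d <- d[sel]
  x <- x[sel]
  if (length(d) == 0) {
    stop("control profile must extend to 100 um", call. = FALSE)
  }
  out <- vapply(levels, function(lv) {
    hit <- which(x <= lv)
    if (length(hit) == 0) return(NA_real_)
    i <- hit[1]
    if (i == 1 || x[i] == lv) return(d[i])
    # linear interpolation across the bracketing pair
    d[i - 1] + (x[i - 1] - lv) / (x[i - 1] - x[i]) * (d[i] - d[i - 1])
  }, numeric(1))
  stats::setNames(out, as.character(levels))
}

# two-sided Dean-Dixon r10 critical values, confidence 0.90/0.95/0.99,
# n = 3..30; cross-checked against a 4e5-replicate Monte-Carlo null of
# Q = max(gap at either extreme)/range under normal sampling
dixon_crit_table <- function(confidence) {
  tab <- list(
    "0.9" = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412,
              0.392, 0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313,
              0.306, 0.300, 0.295, 0.290, 0.285, 0.281, 0.277, 0.273,
              0.269, 0.266, 0.263, 0.260),
    "0.95" = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
               0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
               0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
               0.308, 0.305, 0.301, 0.298),
    "0.99" = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
               0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
               0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
               0.384, 0.380, 0.376, 0.372)
  )
  key <- as.character(confidence)
  if (!key %in% names(tab)) {
    stop("supported confidence levels: 0.9, 0.95, 0.99", call. = FALSE)
  }
  stats::setNames(tab[[key]], 3:30)
}

#' Dixon's Q outlier screen (r10, two-sided, single pass)
#'
#' Computes the classical Dixon Q statistic for the more suspect extreme
#' -- the gap between the extreme and its nearest neighbour divided by
#' the sample range -- and removes at most one value when Q exceeds the
#' two-sided critical value for the sample size at the requested
#' confidence.  Applied only for n of at least 4 (smaller samples and
#' zero-range samples are a no-op); supported up to n = 30.
#'
#' @param values numeric vector.
#' @param confidence confidence level of the critical table, default 0.9.
#' @return Integer vector of indices to remove (length 0 or 1).
#' @export
dixon_outliers <- function(values, confidence = 0.9) {
  n <- length(values)
  if (n < 4) return(integer(0))
  if (n > 30) {
    stop("Dixon's Q critical table supports n up to 30", call. = FALSE)
  }
  rng <- max(values) - min(values)
  if (rng == 0) return(integer(0))
  s <- sort(values)
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  q <- max(q_low, q_high)
  crit <- dixon_crit_table(confidence)[[as.character(n)]]
  if (q <= crit) return(integer(0))
  suspect <- if (q_high >= q_low) which.max(values) else which.min(values)
  as.integer(suspect)
}

#' One-sample significance test of knockdown outgrowth
#'
#' For one gene, the normalized outgrowth intensities measured at the
#' three reference distances are each compared to their level constant
#' (75, 50 or 25) with a two-sided one-sample t-test.  Dixon's Q
#' screening is applied per level beforehand when at least four
#' replicates are available.  Classification: `significant` when any
#' level's p is at most 0.05, `may_influence` when none is but some p is
#' at most 0.1, otherwise `none`; direction (`inhibit`/`stimulate`) from
#' the sign of the mean deviation at the most significant level.
#'
#' @param measurements tibble with columns `gene`, `level` (75/50/25) and
#'   `normalized_intensity` (percent), one row per replicate.
#' @param alpha,alpha_borderline classification cutoffs (0.05 / 0.1).
#' @param dixon_confidence confidence for the outlier screen, 0.9.
#' @return One-row tibble: `gene`, `p_75`, `p_50`, `p_25`,
#'   `classification`, `direction`, `n_used` (replicates used per level,
#'   list column).
#' @export
knockdown_test <- function(measurements, alpha = 0.05,
                           alpha_borderline = 0.1, dixon_confidence = 0.9) {
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("gene", "level", "normalized_intensity") %in%
                  names(measurements)))
  stopifnot(all(measurements$level %in% c(75, 50, 25)))
  gene <- unique(measurements$gene)
  stopifnot(length(gene) == 1)

  res <- lapply(c(75, 50, 25), function(lv) {
    x <- measurements$normalized_intensity[measurements$level == lv]
    if (length(x) >= 4) {
      drop <- dixon_outliers(x, confidence = dixon_confidence)
      if (length(drop) > 0) x <- x[-drop]
    }
    if (length(x) < 2) {
      return(list(p = NA_real_, dev = NA_real_, n = length(x)))
    }
    if (stats::sd(x) == 0) {
      p <- if (mean(x) == lv) 1 else 0
    } else {
      p <- stats::t.test(x, mu = lv)$p.value
    }
    list(p = p, dev = mean(x) - lv, n = length(x))
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  dev <- vapply(res, `[[`, numeric(1), "dev")
  n_used <- vapply(res, `[[`, numeric(1), "n")

  if (all(is.na(p))) {
    return(tibble::tibble(
      gene = gene, p_75 = NA_real_, p_50 = NA_real_, p_25 = NA_real_,
      classification = "undetermined", direction = NA_character_,
      n_used = list(n_used)
    ))
  }
  pmin_v <- min(p, na.rm = TRUE)
  classification <- if (pmin_v <= alpha) {
    "significant"
  } else if (pmin_v <= alpha_borderline) {
    "may_influence"
  } else {
    "none"
  }
  best <- which.min(p)
  direction <- if (classification == "none") {
    NA_character_
  } else if (dev[best] < 0) "inhibit" else "stimulate"
  tibble::tibble(
    gene = gene, p_75 = p[1], p_50 = p[2], p_25 = p[3],
    classification = classification, direction = direction,
    n_used = list(n_used)
  )
}

#' Run the full NOG quantification over one experiment set
#'
#' Convenience driver covering the per-experiment chain: cell-body QC
#' (damaged chambers drop all their profiles; an experiment whose every
#' control fails is dropped entirely), control averaging and
#' normalization, reference-distance lookup, and extraction of the
#' per-gene replicate measurements at the three reference levels.  Genes
#' left with fewer than `min_replicates` measurements per level across
#' experiments are dropped.
#'
#' @param experiments list; each element is one experiment given as a
#'   list with fields `controls` (list of neurite profiles),
#'   `samples` (named list gene -> list of neurite profiles), and
#'   optionally `cell_body` (named list chamber -> cell-body profile,
#'   with control chambers named like their condition).
#' @param levels reference levels, default `c(75, 50, 25)`.
#' @param min_replicates minimum surviving replicates per gene, default 2.
#' @return List with `measurements` (tibble gene/experiment/level/value),
#'   `qc` (tibble chamber-level QC outcomes), `results` (one
#'   [knockdown_test()] row per gene).
#' @export
nog_screen <- function(experiments, levels = c(75, 50, 25),
                       min_replicates = 2) {
  qc_rows <- list()
  meas <- list()
  for (e in seq_along(experiments)) {
    exp <- experiments[[e]]
    exp_id <- if (!is.null(exp$id)) exp$id else as.character(e)
    dropped <- character(0)
    if (!is.null(exp$cell_body)) {
      status <- vapply(exp$cell_body, qc_cell_body, character(1))
      qc_rows[[length(qc_rows) + 1]] <- tibble::tibble(
        experiment = exp_id, chamber = names(status), status = unname(status)
      )
      dropped <- names(status)[status != "pass"]
    }
    controls <- exp$controls
    if (length(dropped) > 0) {
      keep_ctrl <- !vapply(controls, function(p) {
        p$chamber_id %in% dropped
      }, logical(1))
      controls <- controls[keep_ctrl]
    }
    if (length(controls) == 0) next     # whole experiment unusable
    norm <- normalize_to_control(
      profiles = unlist(exp$samples, recursive = FALSE), controls = controls
    )
    refs <- find_reference_distances(norm$control_mean, levels)
    genes <- names(exp$samples)
    k <- 0
    for (g in genes) {
      for (p in exp$samples[[g]]) {
        k <- k + 1
        if (p$chamber_id %in% dropped) next
        sp <- norm$profiles[[k]]
        vals <- profile_value_at(sp, refs)
        meas[[length(meas) + 1]] <- tibble::tibble(
          gene = g, experiment = exp_id, level = levels,
          normalized_intensity = vals
        )
      }
    }
  }
  measurements <- dplyr::bind_rows(meas)
  if (nrow(measurements) == 0) {
    measurements <- tibble::tibble(gene = character(), experiment = character(),
                                   level = numeric(),
                                   normalized_intensity = numeric())
  }
  measurements <- measurements[is.finite(measurements$normalized_intensity), ]
  if (nrow(measurements) > 0) {
    counts <- measurements |>
      dplyr::count(.data$gene, .data$level) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_min = min(.data$n), .groups = "drop")
    keep <- counts$gene[counts$n_min >= min_replicates]
    measurements <- measurements[measurements$gene %in% keep, ]
  }
  results <- if (nrow(measurements) == 0) {
    tibble::tibble(gene = character(), p_75 = numeric(), p_50 = numeric(),
                   p_25 = numeric(), classification = character(),
                   direction = character(), n_used = list())
  } else {
    measurements |>
      dplyr::group_by(.data$gene) |>
      dplyr::group_modify(
        ~ knockdown_test(dplyr::mutate(.x, gene = .y$gene))[-1]
      ) |>
      dplyr::ungroup()
  }
  list(
    measurements = measurements,
    qc = dplyr::bind_rows(qc_rows),
    results = results
  )
}
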