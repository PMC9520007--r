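# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic ontology scenario specification
#'
#' Defaults describe a desk-scale leveled ontology with the structural
#' features of a real cell-biology SCP ontology: four levels of
#' increasingly specific processes, overlapping gene annotations drawn
#' from a shared background, and same-level horizontal interactions with
#' a designated pair of strongly interacting level-2 SCPs.
#'
#' @param n_scps SCPs per level 1..4.
#' @param genes_per_scp annotated genes per SCP, per level (level-1 SCPs
#'   are pure containers).
#' @param background_size size of the background gene universe.
#' @param interactions_per_level horizontal interactions drawn per level
#'   (levels with fewer possible pairs are capped at the pair count).
#' @return List of class `ontology_spec`.
#' @export
ontology_spec <- function(n_scps = c(5, 20, 40, 80),
                          genes_per_scp = c(0, 20, 15, 10),
                          background_size = 5000,
                          interactions_per_level = c(5, 60, 120, 240)) {
  stopifnot(length(n_scps) == 4, length(genes_per_scp) == 4,
            all(genes_per_scp <= background_size))
  structure(as.list(environment()), class = "ontology_spec")
}

#' Generate a synthetic SCP ontology with known ground truth
#'
#' Builds a leveled hierarchy (each SCP below level 1 gets one random
#' parent a level up), overlapping gene annotations sampled from the
#' background, and uniform horizontal interaction strengths.  The ground
#' truth records, per level, which unordered pairs sit in the top 20%
#' (level 2) / 25% (level 3) strength percentile, and designates the
#' single strongest level-2 pair (`strong_pair`) for planting
#' combination signals.
#'
#' @param spec an [ontology_spec()].
#' @param seed integer seed; identical seeds give identical ontologies.
#' @return List `ontology` (an `scp_ontology`) and `truth` (list with
#'   `strong_pair`, `top_pairs` per level).
#' @export
synth_ontology <- function(spec = ontology_spec(), seed = 1) {
  stopifnot(inherits(spec, "ontology_spec"))
  with_seed(seed, {
    background <- sprintf("G%05d", seq_len(spec$background_size))
    ids <- lapply(1:4, function(lv) {
      sprintf("L%d_%03d", lv, seq_len(spec$n_scps[lv]))
    })
    scps <- tibble::tibble(
      scp_id = unlist(ids),
      name = paste("synthetic process", unlist(ids)),
      level = rep(1:4, times = spec$n_scps)
    )
    parents <- dplyr::bind_rows(lapply(2:4, function(lv) {
      tibble::tibble(
        scp_id = ids[[lv]],
        parent_id = sample(ids[[lv - 1]], spec$n_scps[lv], replace = TRUE)
      )
    }))
    annotations <- list()
    for (lv in 1:4) {
      for (id in ids[[lv]]) {
        n <- spec$genes_per_scp[lv]
        annotations[[id]] <- if (n > 0) sample(background, n) else character(0)
      }
    }
    interactions <- dplyr::bind_rows(lapply(1:4, function(lv) {
      n_pairs <- choose(spec$n_scps[lv], 2)
      n_draw <- min(spec$interactions_per_level[lv], n_pairs)
      if (n_draw == 0) return(NULL)
      all_pairs <- utils::combn(ids[[lv]], 2)
      take <- sample(ncol(all_pairs), n_draw)
      tibble::tibble(
        scp_a = all_pairs[1, take], scp_b = all_pairs[2, take],
        level = lv, strength = stats::runif(n_draw)
      )
    }))
    ont <- scp_ontology(scps, parents, annotations, interactions, background)

    top_pairs <- lapply(stats::setNames(2:3, c("level2", "level3")),
                        function(lv) {
      frac <- if (lv == 2) 0.20 else 0.25
      ti <- top_interactions(ont, lv, frac)
      ti[order(-ti$strength), c("scp_a", "scp_b", "strength")]
    })
    strong <- top_pairs$level2[1, ]
    list(
      ontology = ont,
      truth = list(
        strong_pair = c(strong$scp_a, strong$scp_b),
        top_pairs = top_pairs
      )
    )
  })
}

#' Synthetic expression scenario specification
#'
#' The default scenario mirrors a four-time-point treated-vs-control
#' bulk RNA-seq design (2, 4, 6, 8 h): log-normal FPKM-like abundances,
#' uniform raw p-values for null genes, and (optionally) genes of chosen
#' SCPs shifted at chosen time points with small p-values.  A
#' configurable fraction of planted genes receives a fold change drawn
#' between log2(1.3) and log2(1.5) -- detectable under the relaxed but
#' not the stringent fold-change cutoff.
#'
#' @param time_points measurement times (h).
#' @param planted `NULL` for a null-only table, or a data frame with
#'   columns `scp_id`, `time_h`, `direction` (`"up"`/`"down"`),
#'   `effect` (absolute log2 fold change), `n_genes` (genes planted per
#'   SCP; `NA` = all annotated genes).
#' @param effect_sd per-gene jitter of the planted log2 effect.
#' @param null_fc_sd log2 fold-change dispersion of null genes.
#' @param mid_fraction fraction of planted genes re-assigned an effect
#'   uniform in (log2 1.3, log2 1.5).
#' @return List of class `expression_spec`.
#' @export
expression_spec <- function(time_points = c(2, 4, 6, 8), planted = NULL,
                            effect_sd = 0.05, null_fc_sd = 0.1,
                            mid_fraction = 0) {
  structure(as.list(environment()), class = "expression_spec")
}

#' Planted specification for the two-SCP combination scenario
#'
#' Convenience builder for the canonical dynamic-enrichment test case:
#' a few genes of each member of the ontology's designated strong level-2
#' pair upregulated at one time point -- individually weak, jointly
#' strong.
#'
#' @param truth ground truth from [synth_ontology()].
#' @param time_h time point of the planted signal, default 6.
#' @param n_genes genes planted per member SCP, default 3.
#' @param effect absolute log2 fold change, default `log2(1.6)`.
#' @return Data frame suitable for the `planted` field of
#'   [expression_spec()].
#' @export
planted_pair_spec <- function(truth, time_h = 6, n_genes = 3,
                              effect = log2(1.6)) {
  data.frame(
    scp_id = truth$strong_pair, time_h = time_h, direction = "up",
    effect = effect, n_genes = n_genes
  )
}

#' Generate a synthetic expression table with known ground truth
#'
#' @param ontology an `scp_ontology` (planted SCPs must exist in it).
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @return List `table` (tibble gene/time_h/fpkm_treated/fpkm_control/
#'   p/p_adj) and `truth` (tibble of planted gene-time rows with their
#'   true effects and effect class `"strong"` or `"mid"`).
#' @export
synth_expression <- function(ontology, spec = expression_spec(), seed = 1) {
  stopifnot(inherits(spec, "expression_spec"))
  genes <- ontology$background
  with_seed(seed, {
    tab <- tidyr::expand_grid(gene = genes, time_h = spec$time_points)
    n <- nrow(tab)
    control <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    lfc <- stats::rnorm(n, 0, spec$null_fc_sd)
    p <- stats::runif(n)
    truth_rows <- list()

    if (!is.null(spec$planted)) {
      for (i in seq_len(nrow(spec$planted))) {
        pl <- spec$planted[i, ]
        pool <- intersect(ontology$annotations[[pl$scp_id]],
                          ontology$background)
        if (length(pool) == 0) {
          stop("planted SCP has no annotated background genes: ", pl$scp_id,
               call. = FALSE)
        }
        k <- if (is.na(pl$n_genes)) length(pool) else min(pl$n_genes,
                                                          length(pool))
        chosen <- sample(pool, k)
        eff <- abs(pl$effect + stats::rnorm(k, 0, spec$effect_sd))
        cls <- rep("strong", k)
        if (spec$mid_fraction > 0) {
          mid <- stats::runif(k) < spec$mid_fraction
          eff[mid] <- stats::runif(sum(mid), log2(1.3), log2(1.5))
          cls[mid] <- "mid"
        }
        sgn <- if (pl$direction == "up") 1 else -1
        idx <- match(paste(chosen, pl$time_h),
                     paste(tab$gene, tab$time_h))
        lfc[idx] <- sgn * eff
        p[idx] <- 10^stats::runif(k, -6, -4)
        truth_rows[[i]] <- tibble::tibble(
          gene = chosen, scp_id = pl$scp_id, time_h = pl$time_h,
          direction = pl$direction, effect = sgn * eff, class = cls
        )
      }
    }
    treated <- pmax(0, (control + 1) * 2^lfc - 1)
    tab$fpkm_control <- control
    tab$fpkm_treated <- treated
    tab$p <- p
    tab <- tab |>
      dplyr::group_by(.data$time_h) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
      dplyr::ungroup()
    list(table = tab, truth = dplyr::bind_rows(truth_rows))
  })
}

#' Synthetic proteomics scenario specification
#'
#' Emulates a two-run iTRAQ-style design for one treated-vs-vehicle
#' comparison: run 1 carries the treated replicates, run 2 the vehicle
#' replicates, and both runs carry two untreated reference samples for
#' within-run normalization.  Run-level multiplicative batch factors
#' make raw values incomparable across runs until normalized.
#'
#' @param n_proteins proteins measured.
#' @param n_planted proteins shifted in the treated samples.
#' @param shift planted log2 shift, default `log2(1.2)`.
#' @param noise_sd log2-scale measurement noise (technical-replicate
#'   level).
#' @param batch_factors multiplicative factor per run.
#' @param replicates treated/vehicle/untreated samples per run arm.
#' @param peptide_one_fraction fraction of proteins identified by a
#'   single peptide (excluded by the two-peptide filter downstream).
#' @return List of class `proteomics_spec`.
#' @export
proteomics_spec <- function(n_proteins = 400, n_planted = 20,
                            shift = log2(1.2), noise_sd = 0.015,
                            batch_factors = c(1, 3), replicates = 2,
                            peptide_one_fraction = 0.1) {
  structure(as.list(environment()), class = "proteomics_spec")
}

#' Generate a synthetic proteomics table with known ground truth
#'
#' @param spec a [proteomics_spec()].
#' @param seed integer seed.
#' @return List `table` (long tibble protein/peptides/run/sample/role/
#'   value) and `truth` (tibble protein/planted/shift/peptides).
#' @export
synth_proteomics <- function(spec = proteomics_spec(), seed = 1) {
  stopifnot(inherits(spec, "proteomics_spec"))
  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(spec$n_proteins))
    base <- stats::rlnorm(spec$n_proteins, meanlog = 5, sdlog = 1)
    peptides <- ifelse(stats::runif(spec$n_proteins) <
                         spec$peptide_one_fraction, 1L,
                       2L + stats::rpois(spec$n_proteins, 3))
    planted <- sample(proteins, spec$n_planted)

    runs <- length(spec$batch_factors)
    layout <- list()
    for (r in seq_len(runs)) {
      arm <- if (r == 1) "treated" else "vehicle"
      for (i in seq_len(spec$replicates)) {
        layout[[length(layout) + 1]] <-
          list(run = r, sample = sprintf("run%d_%s%d", r, arm, i), role = arm)
        layout[[length(layout) + 1]] <-
          list(run = r, sample = sprintf("run%d_untreated%d", r, i),
               role = "untreated")
      }
    }
    rows <- lapply(layout, function(sm) {
      shift <- ifelse(sm$role == "treated" & proteins %in% planted,
                      spec$shift, 0)
      tibble::tibble(
        protein = proteins,
        peptides = peptides,
        run = sm$run,
        sample = sm$sample,
        role = sm$role,
        value = base * spec$batch_factors[sm$run] *
          2^(shift + stats::rnorm(spec$n_proteins, 0, spec$noise_sd))
      )
    })
    list(
      table = dplyr::bind_rows(rows),
      truth = tibble::tibble(
        protein = proteins,
        planted = proteins %in% planted,
        shift = ifelse(proteins %in% planted, spec$shift, 0),
        peptides = peptides
      )
    )
  })
}

#' Synthetic intensity-profile scenario specification
#'
#' Emulates the microfluidic-chamber outgrowth readout: neurite-side
#' control profiles decaying as `100 * exp(-(d - 100) / lambda)` percent
#' of the 100 um anchor, knockdown profiles scaled by a per-gene effect
#' multiplier, Gaussian measurement noise, and cell-body profiles with a
#' tubulin ridge near the wall that the damage flag either displaces
#' past 50 um (`"displaced"`) or attenuates below the 85% QC threshold
#' (`"attenuated"`).
#'
#' @param genes named numeric vector: gene -> effect multiplier (1 =
#'   no effect; 0.5 halves outgrowth intensity).
#' @param n_experiments independent experiments (one replicate per gene
#'   in each).
#' @param controls_per_experiment control chambers per experiment.
#' @param lambda decay constant (um).
#' @param noise_sd intensity noise (percent-scale units).
#' @param noise_scale correlation scale of the noise (um): Gaussian
#'   deviations are drawn at knots this far apart and interpolated, so
#'   profiles wobble smoothly the way averaged line scans do, rather
#'   than flickering independently at grid resolution.
#' @param raw_step raw measurement spacing before 0.1 um resampling (um).
#' @param coverage neurite-side measured range (um).
#' @param cell_body_coverage cell-body-side measured range (um).
#' @param damaged character vector of chamber labels (`"<gene>"` or
#'   `"control<j>"`) whose cell-body side is damaged.
#' @param damage_type `"displaced"` or `"attenuated"`.
#' @return List of class `profile_spec`.
#' @export
profile_spec <- function(genes = c(GENE1 = 0.5, GENE2 = 1.0),
                         n_experiments = 4, controls_per_experiment = 2,
                         lambda = 200, noise_sd = 5, noise_scale = 100,
                         raw_step = 0.5,
                         coverage = 420, cell_body_coverage = 120,
                         damaged = character(0),
                         damage_type = "displaced") {
  stopifnot(length(genes) >= 1, !is.null(names(genes)))
  damage_type <- match.arg(damage_type, c("displaced", "attenuated"))
  structure(as.list(environment()), class = "profile_spec")
}

# noise-free neurite decay (percent of control anchor at 100 um)
neurite_decay <- function(d, lambda, multiplier = 1) {
  multiplier * 100 * exp(-(d - 100) / lambda)
}

# noise-free cell-body shapes
cell_body_shape <- function(d, damage = "none") {
  switch(damage,
    none = 20 + 100 * exp(-(d - 10)^2 / 18),
    displaced = 20 + 100 * exp(-(d - 70)^2 / 18),
    attenuated = 30 + 70 * d / 100 + 25 * exp(-(d - 20)^2 / 18)
  )
}

#' Generate synthetic chamber profiles with known ground truth
#'
#' Produces, per experiment, raw two-column line scans (as measured),
#' their resampled [intensity_profile()]s arranged for [nog_screen()],
#' and a manifest.  Identical seeds give identical output.
#'
#' @param spec a [profile_spec()].
#' @param seed integer seed.
#' @return List `experiments` (input for [nog_screen()]), `manifest`
#'   (tibble), `truth` (tibble gene/multiplier), `raw` (nested list of
#'   raw scans).
#' @export
synth_profiles <- function(spec = profile_spec(), seed = 1) {
  stopifnot(inherits(spec, "profile_spec"))
  with_seed(seed, {
    d_neu <- seq(0, spec$coverage, by = spec$raw_step)
    d_cb <- seq(0, spec$cell_body_coverage, by = spec$raw_step)
    smooth_noise <- function(d) {
      knots <- seq(min(d) - spec$noise_scale, max(d) + spec$noise_scale,
                   by = spec$noise_scale)
      stats::approx(knots, stats::rnorm(length(knots), 0, spec$noise_sd),
                    xout = d)$y
    }
    make_neu <- function(mult, exp_id, chamber, cond, gene) {
      v <- pmax(0, neurite_decay(d_neu, spec$lambda, mult) +
                  smooth_noise(d_neu))
      list(raw = data.frame(distance = d_neu, intensity = v),
           profile = resample_profile(
             data.frame(d_neu, v), side = "neurite", chamber_id = chamber,
             experiment_id = exp_id, condition = cond, gene = gene))
    }
    make_cb <- function(damage, exp_id, chamber) {
      v <- pmax(0, cell_body_shape(d_cb, damage) + smooth_noise(d_cb))
      resample_profile(data.frame(d_cb, v), side = "cell_body",
                       chamber_id = chamber, experiment_id = exp_id)
    }
    experiments <- list()
    manifest <- list()
    raw <- list()
    for (e in seq_len(spec$n_experiments)) {
      exp_id <- sprintf("E%d", e)
      controls <- list()
      cell_body <- list()
      for (j in seq_len(spec$controls_per_experiment)) {
        lab <- sprintf("control%d", j)
        chamber <- paste(exp_id, lab, sep = "_")
        g <- make_neu(1, exp_id, chamber, "control", NA_character_)
        controls[[j]] <- g$profile
        raw[[chamber]] <- g$raw
        dmg <- if (lab %in% spec$damaged) spec$damage_type else "none"
        cell_body[[chamber]] <- make_cb(dmg, exp_id, chamber)
        manifest[[length(manifest) + 1]] <- tibble::tibble(
          experiment = exp_id, chamber = chamber, condition = "control",
          gene = NA_character_, damaged = dmg != "none"
        )
      }
      samples <- list()
      for (g in names(spec$genes)) {
        chamber <- paste(exp_id, g, sep = "_")
        gg <- make_neu(spec$genes[[g]], exp_id, chamber, "siRNA", g)
        samples[[g]] <- list(gg$profile)
        raw[[chamber]] <- gg$raw
        dmg <- if (g %in% spec$damaged) spec$damage_type else "none"
        cell_body[[chamber]] <- make_cb(dmg, exp_id, chamber)
        manifest[[length(manifest) + 1]] <- tibble::tibble(
          experiment = exp_id, chamber = chamber, condition = "siRNA",
          gene = g, damaged = dmg != "none"
        )
      }
      experiments[[e]] <- list(id = exp_id, controls = controls,
                               samples = samples, cell_body = cell_body)
    }
    list(
      experiments = experiments,
      manifest = dplyr::bind_rows(manifest),
      truth = tibble::tibble(gene = names(spec$genes),
                             multiplier = unname(spec$genes)),
      raw = raw
    )
  })
}

#' Model parameter sets in named feasibility regimes
#'
#' Returns a [model_parameters()] set whose analytic solution lies in
#' the requested zone of the back-transport landscape: `feasible` (well
#' above both thresholds), `near_stall` (just above the stall bound,
#' inside the rapid-increase zone), or `stalled` (below the stall
#' bound, infeasible).  The target velocity is jittered by up to 10%
#' from the seed; the back-transport rate is then placed relative to
#' the analytically computed stall bound and the construction is
#' verified via [analytic_parameter_solution()] before returning.
#'
#' @param regime `"feasible"`, `"near_stall"` or `"stalled"`.
#' @param seed integer seed.
#' @param base base [model_parameters()] to modify.
#' @return A `model_parameters` object with attribute `"stall_bound"`.
#' @export
default_model_params <- function(regime = c("feasible", "near_stall",
                                            "stalled"),
                                 seed = 1, base = model_parameters()) {
  regime <- match.arg(regime)
  with_seed(seed, {
    p <- base
    p$target_velocity <- base$target_velocity * stats::runif(1, 0.9, 1.1)
    v <- p$target_velocity
    phi_s <- 2 * pi * p$neurite_radius * v
    g <- 1 + v / (p$bound_fraction * p$kinesin_speed)
    h <- 1 / (1 + v / p$dynein_speed)
    a <- p$vesicle_area
    bound_for <- function(per_ves, cap, synth) {
      den <- cap * h - per_ves * g
      if (den <= 0) return(Inf)
      max(0, (per_ves * g * phi_s - a * synth) / den)
    }
    stall <- max(bound_for(p$snares_per_vesicle, p$snare_cap,
                           p$snare_synthesis),
                 bound_for(p$receptors_per_vesicle, p$receptor_cap,
                           p$receptor_synthesis))
    p$back_transport_rate <- switch(regime,
      feasible = 2.5 * stall,
      near_stall = 1.03 * stall,
      stalled = 0.6 * stall
    )
    sol <- analytic_parameter_solution(v, p$back_transport_rate, p)
    if (regime == "stalled") {
      stopifnot(!sol$feasible)
    } else {
      stopifnot(sol$feasible)
    }
    if (regime == "near_stall") {
      ref <- analytic_parameter_solution(v, 5 * stall, p)
      stopifnot(sol$required_snare_total >= 2 * ref$required_snare_total)
    }
    attr(p, "stall_bound") <- stall
    p
  })
}
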