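#' Parameters of the vesicle-transport outgrowth model
#'
#' Constructs the parameter set of the compartmental neurite-outgrowth
#' model: membrane and cargo-protein synthesis feed the trans-Golgi
#' network (TGN); anterograde vesicles bud there (each fully equipped
#' with a fixed complement of v-SNAREs and kinesin receptors), travel the
#' shaft on microtubules, fuse at the growth cone and add membrane;
#' endocytosis generates retrograde vesicles that carry cargo (up to a
#' per-vesicle cap) back to the TGN; excess growth-cone membrane converts
#' into shaft length.  Only a fraction of shaft vesicles is
#' microtubule-bound at any time; the rest form a reservoir.
#'
#' Default magnitudes are desk-scale placeholders of the right order
#' (0.5 um shaft radius, 100 nm vesicle diameter, motor speeds of
#' 1 um/s), not measured values; all are plain list entries that can be
#' overridden.
#'
#' @param target_velocity neurite outgrowth velocity to sustain (um/h).
#' @param back_transport_rate membrane area returned from growth cone to
#'   TGN per hour (um^2/h).
#' @param neurite_radius shaft radius (um).
#' @param vesicle_area membrane area of one vesicle (um^2).
#' @param snares_per_vesicle,receptors_per_vesicle copies each
#'   anterograde vesicle must carry to bud.
#' @param snare_cap,receptor_cap maximum copies a (retrograde) vesicle
#'   can bind; per-vesicle equipment may not exceed these.
#' @param kinesin_speed,dynein_speed motor speeds (um/h).
#' @param bound_fraction fraction of shaft anterograde vesicles bound to
#'   microtubules (literature-curated constraint, default 0.10).
#' @param exchange_rate microtubule binding/unbinding relaxation rate
#'   (1/h); large, so the bound share tracks `bound_fraction`.
#' @param budding_rate,fusion_rate,shaft_conversion_rate first-order rate
#'   constants (1/h) of TGN budding, growth-cone fusion, and conversion
#'   of growth-cone membrane into shaft.
#' @param recovery_efficiency fraction of the growth-cone cargo pool a
#'   single endocytic vesicle picks up (dimensionless, before the cap).
#' @param snare_synthesis,receptor_synthesis protein synthesis rates
#'   (copies/h).
#' @param membrane_synthesis_rate membrane synthesis (um^2/h); `NULL`
#'   (default) means "use the analytic steady-flux requirement".
#' @param max_snare_total,max_receptor_total feasibility caps on the
#'   required starting totals (copies).
#' @param initial_length neurite length at simulation start (um).
#' @param endo_km half-saturation of endocytosis on growth-cone membrane
#'   (um^2); keeps the endocytic flux from driving the membrane negative.
#' @return A list of class `model_parameters`.
#' @export
model_parameters <- function(target_velocity = 2,
                             back_transport_rate = 4,
                             neurite_radius = 0.5,
                             vesicle_area = 4 * pi * 0.05^2,
                             snares_per_vesicle = 10,
                             receptors_per_vesicle = 5,
                             snare_cap = 40,
                             receptor_cap = 20,
                             kinesin_speed = 3600,
                             dynein_speed = 3600,
                             bound_fraction = 0.10,
                             exchange_rate = 5e4,
                             budding_rate = 60,
                             fusion_rate = 60,
                             shaft_conversion_rate = 60,
                             recovery_efficiency = 0.01,
                             snare_synthesis = 200,
                             receptor_synthesis = 100,
                             membrane_synthesis_rate = NULL,
                             max_snare_total = 1e5,
                             max_receptor_total = 5e4,
                             initial_length = 20,
                             endo_km = 1e-3) {
  p <- as.list(environment())
  pos <- c("target_velocity", "neurite_radius", "vesicle_area",
           "snares_per_vesicle", "receptors_per_vesicle", "snare_cap",
           "receptor_cap", "kinesin_speed", "dynein_speed", "exchange_rate",
           "budding_rate", "fusion_rate", "shaft_conversion_rate",
           "recovery_efficiency", "max_snare_total", "max_receptor_total",
           "initial_length", "endo_km")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  stopifnot(p$back_transport_rate >= 0,
            p$snare_synthesis >= 0, p$receptor_synthesis >= 0,
            p$bound_fraction > 0, p$bound_fraction <= 1,
            p$snares_per_vesicle <= p$snare_cap,
            p$receptors_per_vesicle <= p$receptor_cap)
  class(p) <- "model_parameters"
  p
}

#' Read model parameters from a YAML or JSON config file
#'
#' @param path config file; keys matching [model_parameters()] arguments.
#' @return A `model_parameters` object.
#' @export
read_model_params <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite required for JSON configs", call. = FALSE)
    }
    jsonlite::fromJSON(path)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  do.call(model_parameters, cfg)
}

#' Analytic steady-flux solution of the outgrowth model
#'
#' Closed-form requirement calculation: for a demanded outgrowth velocity
#' and a membrane back-transport rate, balance all membrane and cargo
#' fluxes of the model at quasi-steady state (constant fluxes; shaft
#' vesicle reservoir and retrograde transit pools growing linearly with
#' the elongating neurite) and report the v-SNARE and kinesin-receptor
#' totals that must be present at simulation start, plus the membrane
#' synthesis rate that sustains the growth.
#'
#' The flux chain: shaft demand `2*pi*radius*velocity` plus the back-
#' transport rate fixes the anterograde arrival flux; transit time,
#' `bound_fraction` and the elongation-driven reservoir growth fix the
#' budding rate and the standing vesicle pools; the cargo each
#' retrograde vesicle must recover is whatever budding consumes beyond
#' de-novo synthesis, divided by the retrograde vesicle flux.  A
#' parameter constellation is infeasible when that per-vesicle recovery
#' exceeds the vesicle's binding-site cap, when a required total exceeds
#' its configured maximum (`violation = "exceeds_max"`), or when any
#' derived quantity is negative (`violation = "negative_parameter"`);
#' infeasibility is a reported outcome, not an error.
#'
#' @param target_velocity outgrowth velocity (um/h); must be positive.
#' @param back_transport_rate membrane back transport (um^2/h).
#' @param params a [model_parameters()] object.
#' @return List of class `feasibility_solution`: `required_snare_total`,
#'   `required_receptor_total`, `required_membrane_synthesis`, `feasible`,
#'   `violation` (`NULL` when feasible), and `detail` (all standing pools
#'   and fluxes, used to initialise [simulate_outgrowth()]).
#' @export
analytic_parameter_solution <- function(target_velocity, back_transport_rate,
                                        params = model_parameters()) {
  stopifnot(target_velocity > 0, back_transport_rate >= 0)
  v <- target_velocity
  b <- back_transport_rate
  a <- params$vesicle_area
  f <- params$bound_fraction
  L0 <- params$initial_length
  sA <- params$snares_per_vesicle
  kA <- params$receptors_per_vesicle

  phi_shaft <- 2 * pi * params$neurite_radius * v
  phi_arr <- phi_shaft + b                   # fusion area flux at the cone
  J_arr <- phi_arr / a                       # vesicles/h reaching the cone
  res_growth <- J_arr * v / (f * params$kinesin_speed)  # dA_shaft/dt
  budding <- J_arr + res_growth              # vesicles/h budding at TGN

  E <- b / a                                 # endocytic vesicles/h
  ret_arr <- E / (1 + v / params$dynein_speed)  # retro vesicles/h at TGN
  ret_growth <- E - ret_arr

  membrane_synthesis <- a * budding - a * ret_arr

  pools <- list(
    M_tgn = a * budding / params$budding_rate,
    A_shaft = J_arr * L0 / (f * params$kinesin_speed),
    A_gc = J_arr / params$fusion_rate,
    R_t = ret_arr * L0 / params$dynein_speed,
    M_gc = phi_shaft / params$shaft_conversion_rate
  )

  per_retro <- function(per_ves, synthesis) {
    consumed <- per_ves * budding - synthesis
    if (consumed <= 0) return(0)
    if (ret_arr <= 0) return(Inf)
    consumed / ret_arr
  }
  s_ret <- per_retro(sA, params$snare_synthesis)
  k_ret <- per_retro(kA, params$receptor_synthesis)

  cargo_total <- function(per_ves, ret_need) {
    tgn <- per_ves * budding / params$budding_rate
    transit <- per_ves * (pools$A_shaft + pools$A_gc)
    gc <- if (is.finite(ret_need)) ret_need / params$recovery_efficiency else Inf
    ret <- if (is.finite(ret_need)) ret_need * pools$R_t else Inf
    c(tgn = tgn, transit = transit, gc = gc, ret = ret)
  }
  s_parts <- cargo_total(sA, s_ret)
  k_parts <- cargo_total(kA, k_ret)
  s_total <- sum(s_parts)
  k_total <- sum(k_parts)

  violation <- NULL
  all_q <- c(unlist(pools), s_ret, k_ret, membrane_synthesis)
  if (any(!is.nan(all_q) & all_q < 0)) {
    violation <- "negative_parameter"
  } else if (s_ret > params$snare_cap || k_ret > params$receptor_cap ||
             s_total > params$max_snare_total ||
             k_total > params$max_receptor_total) {
    violation <- "exceeds_max"
  }

  structure(
    list(
      required_snare_total = s_total,
      required_receptor_total = k_total,
      required_membrane_synthesis = membrane_synthesis,
      feasible = is.null(violation),
      violation = violation,
      detail = list(
        phi_shaft = phi_shaft, phi_arrival = phi_arr, J_arrival = J_arr,
        budding = budding, endocytosis = E, retro_arrival = ret_arr,
        reservoir_growth = res_growth, retro_growth = ret_growth,
        snare_per_retro = s_ret, receptor_per_retro = k_ret,
        pools = pools, snare_parts = s_parts, receptor_parts = k_parts,
        target_velocity = v, back_transport_rate = b
      )
    ),
    class = "feasibility_solution"
  )
}

#' @export
print.feasibility_solution <- function(x, ...) {
  cat("<feasibility_solution>\n")
  cat(sprintf("  velocity %.3g um/h, back transport %.3g um^2/h\n",
              x$detail$target_velocity, x$detail$back_transport_rate))
  cat(sprintf("  required v-SNAREs: %.4g, kinesin receptors: %.4g\n",
              x$required_snare_total, x$required_receptor_total))
  cat(sprintf("  feasible: %s%s\n", x$feasible,
              if (!x$feasible) paste0(" (", x$violation, ")") else ""))
  invisible(x)
}

# initial ODE state from an analytic solution
initial_state_from_solution <- function(sol, params) {
  d <- sol$detail
  p <- d$pools
  L0 <- params$initial_length
  # microtubule-bound share at the exchange/transit balance for L0
  frac0 <- params$bound_fraction * params$exchange_rate /
    (params$exchange_rate + params$kinesin_speed / L0)
  c(
    M_tgn = p$M_tgn,
    A_b = frac0 * p$A_shaft,
    A_r = (1 - frac0) * p$A_shaft,
    A_gc = p$A_gc,
    R_t = p$R_t,
    M_gc = p$M_gc,
    L = L0,
    S_tgn = unname(d$snare_parts["tgn"]),
    K_tgn = unname(d$receptor_parts["tgn"]),
    S_gc = unname(d$snare_parts["gc"]),
    K_gc = unname(d$receptor_parts["gc"]),
    S_ret = unname(d$snare_parts["ret"]),
    K_ret = unname(d$receptor_parts["ret"]),
    cum_m = 0, cum_s = 0, cum_k = 0
  )
}

model_derivs <- function(t, y, p) {
  a <- p$vesicle_area
  B <- p$budding_rate * max(0, min(y["M_tgn"] / a,
                                   y["S_tgn"] / p$snares_per_vesicle,
                                   y["K_tgn"] / p$receptors_per_vesicle))
  bind <- p$exchange_rate * p$bound_fraction * y["A_r"]
  unbind <- p$exchange_rate * (1 - p$bound_fraction) * y["A_b"]
  arr <- y["A_b"] * p$kinesin_speed / y["L"]
  fus <- p$fusion_rate * y["A_gc"]
  E <- (p$back_transport_rate / a) * y["M_gc"] / (y["M_gc"] + p$endo_km)
  s_pick <- min(p$snare_cap, p$recovery_efficiency * y["S_gc"])
  k_pick <- min(p$receptor_cap, p$recovery_efficiency * y["K_gc"])
  ret_arr <- y["R_t"] * p$dynein_speed / y["L"]
  ret_s <- y["S_ret"] * p$dynein_speed / y["L"]
  ret_k <- y["K_ret"] * p$dynein_speed / y["L"]
  shaft <- p$shaft_conversion_rate * y["M_gc"]

  list(c(
    M_tgn = p$membrane_synthesis_rate + a * ret_arr - a * B,
    A_b = bind - unbind - arr,
    A_r = B - bind + unbind,
    A_gc = arr - fus,
    R_t = E - ret_arr,
    M_gc = a * fus - a * E - shaft,
    L = shaft / (2 * pi * p$neurite_radius),
    S_tgn = p$snare_synthesis + ret_s - p$snares_per_vesicle * B,
    K_tgn = p$receptor_synthesis + ret_k - p$receptors_per_vesicle * B,
    S_gc = p$snares_per_vesicle * fus - E * s_pick,
    K_gc = p$receptors_per_vesicle * fus - E * k_pick,
    S_ret = E * s_pick - ret_s,
    K_ret = E * k_pick - ret_k,
    cum_m = p$membrane_synthesis_rate,
    cum_s = p$snare_synthesis,
    cum_k = p$receptor_synthesis
  ))
}

#' Simulate neurite outgrowth by numerical integration
#'
#' Integrates the compartmental vesicle-transport model with
#' `deSolve::lsoda` (stiff-capable, relative tolerance 1e-8; the model is
#' deterministic).  By default the initial state and the membrane
#' synthesis rate are taken from the analytic steady-flux solution for
#' the parameter set, so a feasible configuration starts on its
#' steady-growth trajectory.
#'
#' @param params a [model_parameters()] object.
#' @param initial named state vector, or `NULL` to initialise from
#'   [analytic_parameter_solution()].
#' @param duration simulated hours, default 48.
#' @param n_out number of output time points, default 193.
#' @param rtol,atol integrator tolerances.
#' @return Tibble of the state trajectory with derived columns
#'   `velocity` (um/h, from the shaft-conversion flux),
#'   `bound_percent` (share of shaft anterograde vesicles bound to
#'   microtubules, percent), `membrane_total`, `snare_total`,
#'   `receptor_total` (conserved-quantity audits including cumulative
#'   synthesis).
#' @export
simulate_outgrowth <- function(params = model_parameters(), initial = NULL,
                               duration = 48, n_out = 193,
                               rtol = 1e-8, atol = 1e-8) {
  if (is.null(params$membrane_synthesis_rate) || is.null(initial)) {
    sol <- analytic_parameter_solution(params$target_velocity,
                                       params$back_transport_rate, params)
    if (is.null(params$membrane_synthesis_rate)) {
      params$membrane_synthesis_rate <- sol$required_membrane_synthesis
    }
    if (is.null(initial)) {
      if (!all(is.finite(unlist(sol$detail$snare_parts))) ||
          !all(is.finite(unlist(sol$detail$receptor_parts)))) {
        stop("analytic solution is infeasible (", sol$violation,
             "); supply a finite initial state explicitly", call. = FALSE)
      }
      initial <- initial_state_from_solution(sol, params)
    }
  }
  times <- seq(0, duration, length.out = n_out)
  traj <- deSolve::lsoda(initial, times, model_derivs, params,
                         rtol = rtol, atol = atol)
  bad <- attr(traj, "istate")[1]
  if (bad < 0) stop("integration failed (lsoda istate ", bad, ")",
                    call. = FALSE)
  traj <- tibble::as_tibble(as.data.frame(traj))
  neg <- vapply(traj[c("M_tgn", "A_b", "A_r", "A_gc", "R_t", "M_gc", "L",
                       "S_tgn", "K_tgn", "S_gc", "K_gc", "S_ret", "K_ret")],
                min, numeric(1))
  if (any(neg < -1e-6 * max(abs(unlist(initial))))) {
    stop("state went negative beyond tolerance: ",
         paste(names(neg)[neg < 0], collapse = ", "), call. = FALSE)
  }
  a <- params$vesicle_area
  r2p <- 2 * pi * params$neurite_radius
  dplyr::mutate(
    traj,
    velocity = params$shaft_conversion_rate * .data$M_gc / r2p,
    bound_percent = 100 * .data$A_b / (.data$A_b + .data$A_r),
    membrane_total = .data$M_tgn +
      a * (.data$A_b + .data$A_r + .data$A_gc + .data$R_t) +
      .data$M_gc + r2p * .data$L - .data$cum_m,
    snare_total = .data$S_tgn +
      params$snares_per_vesicle * (.data$A_b + .data$A_r + .data$A_gc) +
      .data$S_gc + .data$S_ret - .data$cum_s,
    receptor_total = .data$K_tgn +
      params$receptors_per_vesicle * (.data$A_b + .data$A_r + .data$A_gc) +
      .data$K_gc + .data$K_ret - .data$cum_k
  )
}

#' Mean outgrowth velocity over the tail of a trajectory
#'
#' @param traj output of [simulate_outgrowth()].
#' @param tail_fraction fraction of the run (from the end) to average
#'   over, default 0.5.
#' @return Velocity in um/h.
#' @export
steady_velocity <- function(traj, tail_fraction = 0.5) {
  n <- nrow(traj)
  i0 <- max(1, floor(n * (1 - tail_fraction)))
  (traj$L[n] - traj$L[i0]) / (traj$time[n] - traj$time[i0])
}

#' Scan velocities and back-transport rates for feasibility thresholds
#'
#' Evaluates [analytic_parameter_solution()] over a velocity x back-rate
#' grid and, per velocity, extracts two thresholds: the *stall*
#' threshold (smallest back rate that is feasible at all) and the
#' *rapid-increase* threshold (smallest feasible back rate at which the
#' required cargo total has fallen to at most `rapid_factor` times its
#' large-back-rate asymptote, operationalised as the required total at
#' the largest back rate of the grid; the definition is recorded in the
#' returned metadata and configurable).
#'
#' @param velocities,back_rates positive numeric grids.
#' @param params a [model_parameters()] object.
#' @param rapid_factor multiple of the asymptote defining the
#'   rapid-increase threshold, default 2.
#' @return List: `surface` (tibble velocity/back_rate/required totals/
#'   feasible/violation), `thresholds` (tibble per velocity and cargo
#'   species), `meta`.
#' @export
scan_backtransport_thresholds <- function(velocities, back_rates,
                                          params = model_parameters(),
                                          rapid_factor = 2) {
  stopifnot(length(velocities) > 0, length(back_rates) > 0,
            all(velocities > 0), all(back_rates > 0))
  back_rates <- sort(back_rates)
  grid <- expand.grid(velocity = sort(velocities), back_rate = back_rates,
                      KEEP.OUT.ATTRS = FALSE)
  sols <- Map(function(v, b) analytic_parameter_solution(v, b, params),
              grid$velocity, grid$back_rate)
  surface <- tibble::tibble(
    velocity = grid$velocity,
    back_rate = grid$back_rate,
    required_snare_total = vapply(sols, `[[`, numeric(1),
                                  "required_snare_total"),
    required_receptor_total = vapply(sols, `[[`, numeric(1),
                                     "required_receptor_total"),
    feasible = vapply(sols, `[[`, logical(1), "feasible"),
    violation = vapply(sols, function(s) {
      if (is.null(s$violation)) NA_character_ else s$violation
    }, character(1))
  )
  b_max <- max(back_rates)
  thresholds <- surface |>
    tidyr::pivot_longer(dplyr::all_of(c("required_snare_total",
                                        "required_receptor_total")),
                        names_to = "species", values_to = "total") |>
    dplyr::mutate(species = ifelse(.data$species == "required_snare_total",
                                   "snare", "receptor")) |>
    dplyr::group_by(.data$velocity, .data$species) |>
    dplyr::summarise(
      threshold_stall = if (any(.data$feasible)) {
        min(.data$back_rate[.data$feasible])
      } else NA_real_,
      asymptote = .data$total[.data$back_rate == b_max & .data$feasible][1],
      threshold_rapid_increase = {
        ok <- .data$feasible & .data$total <= rapid_factor * .data$asymptote
        if (any(ok)) min(.data$back_rate[ok]) else NA_real_
      },
      .groups = "drop"
    )
  list(
    surface = surface,
    thresholds = thresholds,
    meta = list(
      rapid_increase_definition = paste0(
        "smallest feasible back rate with required total <= ", rapid_factor,
        " x the required total at the largest scanned back rate (", b_max,
        " um^2/h)"),
      rapid_factor = rapid_factor
    )
  )
}
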