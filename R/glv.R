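# Ground-truth generator: generalized Lotka-Volterra serial-dilution batch
# culture with mechanism plugins (interference bacteriocin; exclusive
# polysaccharide degradation -> acidification -> pH exclusion), plus the qPCR
# observation model. The generator is test scaffolding with known ground
# truth, not an inference claim about any real community.
#
# Dynamics within one 24 h batch passage, per environment:
#   dx_i/dt = x_i * (mu_i * g_i(pH) + sum_j a_ij x_j + yield_i * R)
#             - sum_p k_pi * x_p * x_i
#   dR/dt   = -c * x_deg * R
#   pH(t)   = pH0 - gamma * (R0 - R(t)) - sum_i w_i * x_i / (x_i + h)
# g_i is a logistic switch at strain i's pH threshold (NA = insensitive);
# the smooth switch avoids integrator discontinuities. At each passage
# boundary abundances are divided by the dilution factor, populations below
# the extinction floor are set to exact 0, and the resource pool is reset to
# fresh. Communities are sampled at the end of the final passage (96 h under
# the default 4 x 24 h schedule).

default_passaging <- function() {
  list(dilution = 100, hours = 24, n_passages = 4L)
}

default_observation <- function() {
  list(noise_sdlog = 0.2,   # multiplicative lognormal qPCR noise
       jitter_sdlog = 0.1,  # biological-replicate inoculum variation
       ph_sd = 0.05,        # pH meter noise, pH units
       n_bio = 3L, n_tech = 3L,
       gdna_conc = 20, elution_volume = 150, template_mass = 5,
       sample_amount = 1)
}

#' Bacteriocin interference mechanism plugin
#'
#' The producer kills sensitive strains at rate `kill_rate * x_producer`
#' (mass-action interference, an enterocin-like leaderless bacteriocin).
#'
#' @param producer producer strain_id.
#' @param targets character vector of sensitive strain_ids.
#' @param kill_rate kill rate per unit producer abundance per hour (>= 0).
#' @return mechanism plugin list.
#' @export
mechanism_bacteriocin <- function(producer, targets, kill_rate) {
  if (kill_rate < 0) stopf("kill_rate must be >= 0")
  list(kind = "bacteriocin", producer = producer, targets = targets,
       kill_rate = kill_rate)
}

#' Exclusive-resource acidification mechanism plugin
#'
#' One strain exclusively degrades a polysaccharide pool (inulin-like),
#' gaining extra growth, and the fermentation acids lower the culture pH by
#' `gamma` per g/L consumed. pH-sensitive strains (thresholds set in the
#' environment) lose their growth once the pH falls below their threshold.
#'
#' @param degrader degrader strain_id.
#' @param R0 fresh-medium resource concentration, g/L.
#' @param consumption_rate resource consumption per unit degrader abundance
#'   per hour.
#' @param yield extra specific growth rate of the degrader per g/L resource.
#' @param gamma pH drop per g/L of resource consumed.
#' @return mechanism plugin list.
#' @export
mechanism_exclusive_resource <- function(degrader, R0 = 2,
                                         consumption_rate = 2e-9,
                                         yield = 0.15, gamma = 0.5) {
  stopifnot(R0 >= 0, consumption_rate >= 0, yield >= 0)
  list(kind = "exclusive_resource_acidification", degrader = degrader,
       R0 = R0, consumption_rate = consumption_rate, yield = yield,
       gamma = gamma)
}

#' Environment parameter set for the simulator
#'
#' @param mu named vector of maximal specific growth rates, 1/h.
#' @param A interaction matrix (row = affected, column = acting strain);
#'   diagonal must be negative (self-limitation, `-mu_i / K_i`).
#' @param inoculum named vector of initial abundances at the start of each
#'   experiment, copies/ml.
#' @param ph0 fresh-medium pH.
#' @param acid_weights named vector: saturating per-strain pH contribution
#'   (pH units at full occupancy).
#' @param acid_half half-saturation abundance of the acid contribution.
#' @param ph_thresholds named vector of pH growth thresholds (NA =
#'   insensitive).
#' @param ph_steepness steepness of the logistic pH switch.
#' @param mechanisms list of mechanism plugins.
#' @return environment parameter list.
#' @export
glv_environment <- function(mu, A, inoculum, ph0 = 7.0,
                            acid_weights = NULL, acid_half = 5e7,
                            ph_thresholds = NULL, ph_steepness = 8,
                            mechanisms = list()) {
  n <- length(mu)
  stopifnot(nrow(A) == n, ncol(A) == n, length(inoculum) == n)
  if (any(diag(A) >= 0)) stopf("self-limitation a_ii must be < 0 for all strains")
  if (any(!is.finite(mu)) || any(!is.finite(A))) stopf("rates must be finite")
  ids <- names(mu)
  acid_weights <- acid_weights %||% stats::setNames(rep(0, n), ids)
  ph_thresholds <- ph_thresholds %||% stats::setNames(rep(NA_real_, n), ids)
  for (m in mechanisms) {
    who <- switch(m$kind, bacteriocin = c(m$producer, m$targets),
                  exclusive_resource_acidification = m$degrader)
    if (!all(who %in% ids)) stopf("mechanism references strains not in mu")
  }
  list(mu = mu, A = A, inoculum = inoculum, ph0 = ph0,
       acid_weights = acid_weights[ids], acid_half = acid_half,
       ph_thresholds = ph_thresholds[ids], ph_steepness = ph_steepness,
       mechanisms = mechanisms)
}

#' Simulation scenario: roster, environments, passaging and observation model
#'
#' @param roster a `strain_roster`.
#' @param environments named list of [glv_environment()] parameter sets.
#' @param passaging list with `dilution` (> 1), `hours`, `n_passages`.
#' @param observation list with `noise_sdlog`, `jitter_sdlog`, `ph_sd`,
#'   `n_bio`, `n_tech` and the qPCR back-transformation constants.
#' @param extinction_floor abundance below which a population is set to
#'   exact 0 at passage boundaries.
#' @return list of class `simulation_scenario`.
#' @export
glv_scenario <- function(roster, environments,
                         passaging = default_passaging(),
                         observation = default_observation(),
                         extinction_floor = 1e-2) {
  stopifnot(inherits(roster, "strain_roster"))
  if (passaging$dilution <= 1) stopf("dilution factor must be > 1")
  structure(list(roster = roster, environments = environments,
                 passaging = passaging, observation = observation,
                 extinction_floor = extinction_floor),
            class = "simulation_scenario")
}

env_resource <- function(env) {
  for (m in env$mechanisms) {
    if (m$kind == "exclusive_resource_acidification") return(m)
  }
  NULL
}

culture_ph <- function(x, R, env) {
  res <- env_resource(env)
  drop_res <- if (is.null(res)) 0 else res$gamma * (res$R0 - R)
  env$ph0 - drop_res - sum(env$acid_weights * x / (x + env$acid_half))
}

glv_deriv <- function(t, state, parms) {
  env <- parms$env
  n <- length(env$mu)
  x <- pmax(state[seq_len(n)], 0)
  R <- max(state[n + 1L], 0)
  ph <- culture_ph(x, R, env)
  g <- ifelse(is.na(env$ph_thresholds), 1,
              1 / (1 + exp(-env$ph_steepness * (ph - env$ph_thresholds))))
  growth <- env$mu * g + drop(env$A %*% x)
  dR <- 0
  for (m in env$mechanisms) {
    if (m$kind == "bacteriocin") {
      ti <- match(m$targets, names(env$mu))
      pi <- match(m$producer, names(env$mu))
      growth[ti] <- growth[ti] - m$kill_rate * x[pi]
    } else if (m$kind == "exclusive_resource_acidification") {
      di <- match(m$degrader, names(env$mu))
      growth[di] <- growth[di] + m$yield * R
      dR <- dR - m$consumption_rate * x[di] * R
    }
  }
  list(c(x * growth, dR))
}

#' Integrate one batch passage
#'
#' @param x named vector of strain abundances at passage start.
#' @param R resource concentration at passage start (ignored when the
#'   environment has no resource mechanism).
#' @param env a [glv_environment()] parameter set.
#' @param hours passage length (default 24).
#' @param rtol,atol integrator tolerances (stiff-safe lsoda).
#' @return list with end-of-passage `x`, `R` and `ph`.
#' @export
simulate_passage <- function(x, R, env, hours = 24,
                             rtol = 1e-8, atol = 1e-2) {
  if (any(x < 0)) stopf("state must be non-negative")
  sol <- deSolve::ode(y = c(x, R = R), times = c(0, hours), func = glv_deriv,
                      parms = list(env = env), method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stopf("integrator failure; state: %s",
          paste(sprintf("%s=%.3g", names(x), x), collapse = " "))
  }
  end <- sol[nrow(sol), -1L]
  n <- length(x)
  x_end <- pmax(end[seq_len(n)], 0)
  R_end <- max(end[n + 1L], 0)
  list(x = stats::setNames(x_end, names(x)), R = R_end,
       ph = culture_ph(x_end, R_end, env))
}

#' Simulate one community culture through the full passaging schedule
#'
#' Runs `n_passages` batch cycles with 1:dilution transfers into fresh
#' medium (resource reset, sub-floor populations set to exact 0) and returns
#' the end-of-experiment state.
#'
#' @param scenario a `simulation_scenario`.
#' @param environment environment name within the scenario.
#' @param members strain_ids present in the inoculum (community design).
#' @param inoculum optional named abundance vector overriding the
#'   environment default (e.g. jittered per biological replicate).
#' @return list with final `x`, `ph`, `delta_ph` (vs. fresh medium) and `R`.
#' @export
simulate_community <- function(scenario, environment, members,
                               inoculum = NULL) {
  env <- scenario$environments[[environment]]
  if (is.null(env)) stopf("unknown environment '%s'", environment)
  ids <- names(env$mu)
  x <- stats::setNames(rep(0, length(ids)), ids)
  x0 <- inoculum %||% env$inoculum
  x[members] <- x0[members]
  res <- env_resource(env)
  R0 <- if (is.null(res)) 0 else res$R0
  pas <- scenario$passaging
  R <- R0
  for (p in seq_len(pas$n_passages)) {
    out <- simulate_passage(x, R, env, hours = pas$hours)
    x <- out$x
    if (p < pas$n_passages) {
      x <- x / pas$dilution
      x[x < scenario$extinction_floor] <- 0
      R <- R0
    }
  }
  list(x = x, ph = out$ph, delta_ph = out$ph - env$ph0, R = out$R)
}

#' Run a full dropout experiment on a scenario
#'
#' Simulates the full consortium plus every single-strain dropout community
#' in every environment, with `n_bio` independently jittered inocula and
#' `n_tech` observation wells per inoculum, applies the qPCR observation
#' model (lognormal noise, strain-specific detection limits, normalization
#' round-trip) and returns the observed data alongside the ground truth.
#' All randomness derives from named substreams of `seed`.
#'
#' @param scenario a `simulation_scenario`.
#' @param seed master seed (integer).
#' @param communities optional character vector of community labels to run
#'   (default: `"full"` plus one dropout per roster strain).
#' @return list of class `dropout_experiment`: `abundance`
#'   (an `abundance_table`), `ph` (per-well pH records), `truth`
#'   (per community x environment true endpoint abundances and delta-pH),
#'   `scenario`, `seed`.
#' @export
run_experiment <- function(scenario, seed = 1, communities = NULL) {
  roster <- scenario$roster
  obs <- scenario$observation
  communities <- communities %||%
    c("full", paste0("drop_", roster$strain_id))
  entries <- list(); samples <- list(); ph_rec <- list(); truth <- list()
  for (envname in names(scenario$environments)) {
    env <- scenario$environments[[envname]]
    for (cm in communities) {
      drop <- if (cm == "full") NULL else sub("^drop_", "", cm)
      members <- setdiff(roster$strain_id, drop)
      for (b in seq_len(obs$n_bio)) {
        x0 <- with_substream(seed, paste("jitter", envname, cm, b), {
          env$inoculum * stats::rlnorm(length(env$inoculum), 0, obs$jitter_sdlog)
        })
        names(x0) <- names(env$inoculum)
        sim <- simulate_community(scenario, envname, members, inoculum = x0)
        if (b == 1L) {
          truth[[paste(envname, cm)]] <- data.frame(
            environment = envname, community = cm,
            strain_id = names(sim$x), true_abundance = unname(sim$x),
            true_delta_ph = sim$delta_ph, stringsAsFactors = FALSE)
        }
        for (tc in seq_len(obs$n_tech)) {
          sid <- paste(envname, cm, b, tc, sep = "_")
          well <- with_substream(seed, paste("obs", envname, cm, b, tc), {
            copies <- simulate_readout(
              sim$x[members], gdna_conc = obs$gdna_conc,
              elution_volume = obs$elution_volume,
              template_mass = obs$template_mass,
              n_16S = roster$n_16S[match(members, roster$strain_id)],
              sample_amount = obs$sample_amount,
              noise_sdlog = obs$noise_sdlog)
            # instrument reporting precision: 6 significant digits
            copies <- signif(copies, 6)
            ph_obs <- sim$ph + stats::rnorm(1, 0, obs$ph_sd)
            list(copies = copies, ph = ph_obs)
          })
          norm <- normalize_qpcr(
            well$copies, gdna_conc = obs$gdna_conc,
            elution_volume = obs$elution_volume,
            template_mass = obs$template_mass,
            n_16S = roster$n_16S[match(members, roster$strain_id)],
            sample_amount = obs$sample_amount,
            dtl = roster$dtl[match(members, roster$strain_id)])
          entries[[sid]] <- data.frame(
            sample_id = sid, strain_id = members,
            value = norm$value, censored = norm$censored,
            stringsAsFactors = FALSE)
          samples[[sid]] <- data.frame(
            sample_id = sid, community = cm, environment = envname,
            bio_replicate = b, tech_replicate = tc,
            amount = obs$sample_amount, stringsAsFactors = FALSE)
          ph_rec[[sid]] <- data.frame(
            sample_id = sid, community = cm, environment = envname,
            bio_replicate = b, tech_replicate = tc,
            ph_spent = well$ph, ph_fresh = env$ph0, stringsAsFactors = FALSE)
        }
      }
    }
  }
  at <- abundance_table(do.call(rbind, entries), do.call(rbind, samples),
                        roster)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ph_rec <- do.call(rbind, ph_rec)
  rownames(ph_rec) <- NULL
  structure(list(abundance = at, ph = ph_rec, truth = truth,
                 scenario = scenario, seed = seed),
            class = "dropout_experiment")
}

#' Zero a scenario's bacteriocin kill rates (toxin-knockout analogue)
#'
#' @param scenario a `simulation_scenario`.
#' @return the modified scenario.
#' @export
ablate_bacteriocin <- function(scenario) {
  for (e in names(scenario$environments)) {
    mechs <- scenario$environments[[e]]$mechanisms
    for (i in seq_along(mechs)) {
      if (mechs[[i]]$kind == "bacteriocin") mechs[[i]]$kill_rate <- 0
    }
    scenario$environments[[e]]$mechanisms <- mechs
  }
  scenario
}

#' Zero a scenario's resource acidification (pH-neutralized analogue)
#'
#' Sets `gamma = 0` so that resource degradation no longer lowers the pH;
#' the degrader keeps its growth benefit.
#'
#' @param scenario a `simulation_scenario`.
#' @return the modified scenario.
#' @export
ablate_acidification <- function(scenario) {
  for (e in names(scenario$environments)) {
    mechs <- scenario$environments[[e]]$mechanisms
    for (i in seq_along(mechs)) {
      if (mechs[[i]]$kind == "exclusive_resource_acidification") {
        mechs[[i]]$gamma <- 0
      }
    }
    scenario$environments[[e]]$mechanisms <- mechs
  }
  scenario
}
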