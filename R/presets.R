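# Preset simulation scenarios embodying the two discovered keystone
# mechanisms, plus fast observation-level generators (null and planted-effect
# datasets) used for statistical calibration.
#
# Presets (12-strain roster, 3 biological x 3 technical replicates, 96 h with
# 1:100 serial dilution every 24 h, lognormal qPCR noise sdlog 0.2):
#   neutral                 no interactions, no mechanisms: every dropout is
#                           statistically identical to the full consortium.
#   AF_like_bacteriocin     glucose-like medium: the enterococcal producer
#                           excludes one strain via a bacteriocin and
#                           suppresses four more by competition.
#   APF_like_acidification  polysaccharide-like medium: the Bacteroides-like
#                           degrader has exclusive access to an inulin-like
#                           pool; fermentation acids drop the pH and exclude
#                           a pH-sensitive strain.
#   combined_two_media      both environments in one scenario (the
#                           two-media dropout experiment design).

omm_mu <- function(ids) {
  stats::setNames(c(0.35, 0.45, 0.50, 0.40, 0.30, 0.35,
                    0.40, 0.30, 0.30, 0.45, 0.60, 0.25), ids)
}

omm_K <- function(ids) {
  stats::setNames(c(4e8, 2e9, 6e8, 5e8, 6e8, 3e8,
                    5e8, 3e8, 3e8, 1e9, 1.5e9, 2e8), ids)
}

base_interactions <- function(mu, K) {
  n <- length(mu)
  A <- matrix(0, n, n, dimnames = list(names(mu), names(mu)))
  diag(A) <- -mu / K
  A
}

# a_yx setting the equilibrium of y in the presence of x at (1 + frac) K_y;
# frac = -0.75 gives ~4-fold suppression, +1.5 gives ~2.5-fold support.
push <- function(A, mu, K, y, x, frac) {
  A[y, x] <- frac * mu[y] / K[x]
  A
}

af_like_environment <- function(roster) {
  ids <- roster$strain_id
  mu <- omm_mu(ids); K <- omm_K(ids)
  A <- base_interactions(mu, K)
  # competition by the bacteriocin producer on four community members
  for (y in c("C.in", "L.re", "E.cl")) A <- push(A, mu, K, y, "E.fa", -0.75)
  A <- push(A, mu, K, "F.pl", "E.fa", -1.2)
  # the degrader suppresses one strain in the glucose medium
  A <- push(A, mu, K, "T.mu", "B.ca", -0.75)
  # cross-feeding support by the acetogen
  A <- push(A, mu, K, "M.in", "B.co", 1.5)
  A <- push(A, mu, K, "F.pl", "B.co", 1.5)
  w <- stats::setNames(rep(0.05, length(ids)), ids)
  w[c("C.in", "L.re", "F.pl", "E.cl")] <- 0.12
  w["B.an"] <- 0.18
  w["E.fa"] <- 0.10
  w["B.ca"] <- 0.20
  w["B.co"] <- 0.18
  w["M.in"] <- 0.12
  glv_environment(
    mu = mu, A = A,
    inoculum = stats::setNames(rep(1e7, length(ids)), ids),
    ph0 = 7.0, acid_weights = w, acid_half = 5e7,
    mechanisms = list(
      mechanism_bacteriocin("E.fa", "B.an", kill_rate = 8e-9)))
}

apf_like_environment <- function(roster, enterocin = TRUE) {
  ids <- roster$strain_id
  mu <- omm_mu(ids); K <- omm_K(ids)
  A <- base_interactions(mu, K)
  if (enterocin) {
    for (y in c("C.in", "L.re", "E.cl")) A <- push(A, mu, K, y, "E.fa", -0.75)
    A <- push(A, mu, K, "F.pl", "E.fa", -1.2)
  } else {
    # mechanism-isolation variant: only residual substrate competition by
    # the producer, no interference toxin
    for (y in c("L.re", "E.cl")) A <- push(A, mu, K, y, "E.fa", -0.75)
  }
  # competition by the polysaccharide degrader on three community members
  for (y in c("C.in", "T.mu", "A.muc")) A <- push(A, mu, K, y, "B.ca", -0.75)
  A <- push(A, mu, K, "F.pl", "B.co", 1.5)
  w <- stats::setNames(rep(0.06, length(ids)), ids)
  thr <- stats::setNames(rep(NA_real_, length(ids)), ids)
  thr["M.in"] <- 6.3
  mechs <- list(
    mechanism_exclusive_resource("B.ca", R0 = 2, consumption_rate = 2e-9,
                                 yield = 0.15, gamma = 0.5))
  if (enterocin) {
    mechs <- c(list(mechanism_bacteriocin("E.fa", "B.an", kill_rate = 8e-9)),
               mechs)
  }
  glv_environment(
    mu = mu, A = A,
    inoculum = stats::setNames(rep(1e7, length(ids)), ids),
    ph0 = 7.0, acid_weights = w, acid_half = 5e7,
    ph_thresholds = thr,
    mechanisms = mechs)
}

neutral_environment <- function(roster) {
  ids <- roster$strain_id
  mu <- omm_mu(ids); K <- omm_K(ids)
  glv_environment(mu = mu, A = base_interactions(mu, K),
                  inoculum = stats::setNames(rep(1e7, length(ids)), ids),
                  ph0 = 7.0)
}

#' Preset simulation scenarios
#'
#' @param name one of `"neutral"`, `"AF_like_bacteriocin"`,
#'   `"APF_like_acidification"`, `"combined_two_media"`.
#' @param roster roster to simulate (default [omm12_roster()]).
#' @return a `simulation_scenario`.
#' @export
preset_scenario <- function(name = c("neutral", "AF_like_bacteriocin",
                                     "APF_like_acidification",
                                     "combined_two_media"),
                            roster = omm12_roster()) {
  name <- match.arg(name)
  envs <- switch(name,
    neutral = list(AF = neutral_environment(roster)),
    AF_like_bacteriocin = list(AF = af_like_environment(roster)),
    APF_like_acidification = list(APF = apf_like_environment(roster,
                                                            enterocin = FALSE)),
    combined_two_media = list(AF = af_like_environment(roster),
                              APF = apf_like_environment(roster)))
  glv_scenario(roster, envs)
}

#' Fast observation-level null dataset (dropout == full)
#'
#' Draws dropout and full-consortium replicate groups from the *same*
#' lognormal observation distribution around a shared true abundance vector,
#' bypassing the dynamics. Used to calibrate the false-positive rate of the
#' per-strain Wilcoxon test.
#'
#' @param true_abund named vector of true abundances.
#' @param n_rep wells per group (default 9).
#' @param noise_sdlog observation noise (default 0.2).
#' @return list with matrices `dropout` and `full` (strains x replicates).
#' @export
simulate_null_groups <- function(true_abund, n_rep = 9, noise_sdlog = 0.2) {
  n <- length(true_abund)
  draw <- function() true_abund * matrix(stats::rlnorm(n * n_rep, 0, noise_sdlog),
                                         n, n_rep)
  list(dropout = draw(), full = draw())
}

#' Fast observation-level planted-effect dataset
#'
#' As [simulate_null_groups()], but the dropout group's true abundances are
#' multiplied by `fold` for the planted strains (fold > 1: the strain rises
#' when the focal strain is removed, i.e. a negative relationship).
#'
#' @param true_abund named vector of true abundances of the non-focal strains.
#' @param planted indices or names of affected strains.
#' @param fold abundance fold change in the dropout (default 4).
#' @param n_rep,noise_sdlog observation model.
#' @return list with `dropout`, `full`, and `planted` (names).
#' @export
simulate_planted_groups <- function(true_abund, planted, fold = 4,
                                    n_rep = 9, noise_sdlog = 0.2) {
  shifted <- true_abund
  shifted[planted] <- shifted[planted] * fold
  n <- length(true_abund)
  noise <- function() matrix(stats::rlnorm(n * n_rep, 0, noise_sdlog), n, n_rep)
  list(dropout = shifted * noise(), full = true_abund * noise(),
       planted = names(true_abund[planted]) %||% planted)
}

#' Planted-effect keystone recovery rates
#'
#' Repeatedly simulates observation-level dropout datasets with `n_planted`
#' strains shifted `fold`-fold and counts how often the affected-species
#' count equals the planted count, using the raw-p convention of
#' [keystone_impact()] and, alongside, the BH-adjusted count.
#'
#' @param n_sims number of simulated experiments.
#' @param seed master seed.
#' @param n_strains non-focal community size (default 11).
#' @param n_planted number of affected strains (default 3).
#' @param fold planted abundance fold change (default 4).
#' @param n_rep wells per group (default 9).
#' @param noise_sdlog observation noise (default 0.2).
#' @param alpha significance level (default 0.05).
#' @return named numeric vector: `raw` and `bh` are the fractions of
#'   simulations whose affected count exactly equals `n_planted` under the
#'   raw-p and BH-adjusted conventions; `power` is the fraction in which
#'   every planted strain was individually detected (raw p < alpha).
#' @export
keystone_recovery_rates <- function(n_sims = 200, seed = 1, n_strains = 11,
                                    n_planted = 3, fold = 4, n_rep = 9,
                                    noise_sdlog = 0.2, alpha = 0.05) {
  hits_raw <- hits_bh <- hits_power <- logical(n_sims)
  with_substream(seed, "keystone_recovery", {
    true_abund <- stats::setNames(stats::rlnorm(n_strains, log(1e7), 1),
                                  paste0("S", seq_len(n_strains)))
    for (i in seq_len(n_sims)) {
      g <- simulate_planted_groups(true_abund, seq_len(n_planted),
                                   fold = fold, n_rep = n_rep,
                                   noise_sdlog = noise_sdlog)
      p <- groupwise_shift_pvalues(g)
      hits_raw[i] <- sum(p < alpha) == n_planted
      hits_bh[i] <- sum(stats::p.adjust(p, "BH") < alpha) == n_planted
      hits_power[i] <- all(p[seq_len(n_planted)] < alpha)
    }
  })
  c(raw = mean(hits_raw), bh = mean(hits_bh), power = mean(hits_power))
}

#' Per-strain Wilcoxon p-values for a two-group dataset
#'
#' @param groups list with strain x replicate matrices `dropout` and `full`
#'   (as from [simulate_null_groups()]).
#' @return numeric vector of two-sided p-values, one per strain.
#' @export
groupwise_shift_pvalues <- function(groups) {
  vapply(seq_len(nrow(groups$dropout)), function(i) {
    test_abundance_shift(groups$dropout[i, ], groups$full[i, ])
  }, numeric(1))
}
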