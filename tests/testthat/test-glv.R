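# The serial-dilution gLV generator and its mechanism plugins.

single_strain_env <- function(mu = 0.4, K = 1e9, x0 = 1e6) {
  aii <- -max(mu, 1e-12) / K
  A <- matrix(aii, 1, 1, dimnames = list("S1", "S1"))
  glv_environment(mu = c(S1 = mu), A = A, inoculum = c(S1 = x0))
}

test_that("a lone strain follows the closed-form logistic solution", {
  mu <- 0.4; K <- 1e9; x0 <- 1e6; t <- 24
  env <- single_strain_env(mu, K, x0)
  out <- simulate_passage(c(S1 = x0), R = 0, env = env, hours = t)
  logistic <- K * x0 * exp(mu * t) / (K + x0 * (exp(mu * t) - 1))
  expect_equal(out$x[["S1"]], logistic, tolerance = 1e-6)
})

test_that("zero growth leaves the state unchanged and dilution is exact", {
  env <- single_strain_env(mu = 0, K = 1e30, x0 = 1e6)
  out <- simulate_passage(c(S1 = 1e6), 0, env)
  expect_equal(out$x[["S1"]], 1e6, tolerance = 1e-9)

  # a passage boundary divides by exactly the dilution factor and resets R
  sc <- glv_scenario(strain_roster("S1"), list(E = single_strain_env()),
                     passaging = list(dilution = 100, hours = 24,
                                      n_passages = 2L))
  two <- simulate_community(sc, "E", "S1")
  p1 <- simulate_passage(c(S1 = 1e6), 0, sc$environments$E)
  p2 <- simulate_passage(p1$x / 100, 0, sc$environments$E)
  expect_equal(two$x, p2$x, tolerance = 1e-10)
})

test_that("competitive communities stay bounded and non-negative", {
  set.seed(61)
  roster <- toy_roster(6, dtl = 10)
  mu <- setNames(runif(6, 0.2, 0.6), roster$strain_id)
  K <- setNames(runif(6, 1e8, 1e9), roster$strain_id)
  A <- -abs(matrix(rnorm(36, 0, 1e-10), 6, 6,
                   dimnames = list(roster$strain_id, roster$strain_id)))
  diag(A) <- -mu / K
  env <- glv_environment(mu, A, setNames(rep(1e6, 6), roster$strain_id))
  sc <- glv_scenario(roster, list(E = env))
  out <- simulate_community(sc, "E", roster$strain_id)
  expect_true(all(out$x >= 0))
  expect_true(all(is.finite(out$x)))
  expect_lt(max(out$x), 2 * max(K))
})

test_that("tightening the integrator tolerance barely moves the endpoint", {
  sc <- preset_scenario("APF_like_acidification")
  ids <- sc$roster$strain_id
  env <- sc$environments$APF
  x0 <- env$inoculum
  a <- simulate_passage(x0, 2, env, rtol = 1e-8)
  b <- simulate_passage(x0, 2, env, rtol = 1e-11)
  keep <- b$x > 1 # compare populations above one copy/ml
  expect_lt(max(abs(a$x[keep] - b$x[keep]) / b$x[keep]), 1e-6)
})

test_that("neutral dropouts give r_abs 1 and zero keystone impact", {
  roster <- omm12_roster()
  sc <- preset_scenario("neutral", roster)
  sc$observation$noise_sdlog <- 0
  sc$observation$jitter_sdlog <- 0
  exp <- run_experiment(sc, seed = 1,
                        communities = c("full", "drop_E.fa", "drop_B.ca"))
  rel <- relationship_matrix(exp$abundance)
  ratios <- rel$r_abs[!is.na(rel$r_abs)]
  expect_true(all(abs(ratios - 1) < 1e-9))
  ki <- keystone_impact(rel)
  expect_true(all(ki$n_affected == 0))
})

test_that("acidification excludes the pH-sensitive strain; neutralization rescues it", {
  sc <- preset_scenario("APF_like_acidification")
  ids <- sc$roster$strain_id
  full <- simulate_community(sc, "APF", ids)
  drop <- simulate_community(sc, "APF", setdiff(ids, "B.ca"))
  # detection bound for M.in on the abundance scale: dtl * extract / n_16S
  i <- match("M.in", sc$roster$strain_id)
  dtl_norm <- sc$roster$dtl[i] * (20 * 150 / 5) / sc$roster$n_16S[i]
  expect_lt(full$x[["M.in"]], dtl_norm)       # excluded with the degrader
  expect_gt(drop$x[["M.in"]], 1e7)            # thrives without it
  expect_lt(full$delta_ph, -1)
  expect_gt(drop$delta_ph, -0.7)

  # gamma = 0: resource still consumed but pH no longer falls -> coexistence
  sc0 <- ablate_acidification(sc)
  full0 <- simulate_community(sc0, "APF", ids)
  expect_gt(full0$x[["M.in"]], 1e7)
})

test_that("bacteriocin suppresses its target; knocking it out abolishes the call", {
  sc <- preset_scenario("AF_like_bacteriocin")
  exp <- run_experiment(sc, seed = 7, communities = c("full", "drop_E.fa"))
  rel <- relationship_matrix(exp$abundance)
  ban <- rel[rel$affected_y == "B.an", ]
  expect_equal(ban$category, "exclusion")

  sc0 <- ablate_bacteriocin(sc)
  exp0 <- run_experiment(sc0, seed = 7, communities = c("full", "drop_E.fa"))
  rel0 <- relationship_matrix(exp0$abundance)
  ban0 <- rel0[rel0$affected_y == "B.an", ]
  expect_false(ban0$category %in% c("exclusion", "negative") && ban0$significant)
})

test_that("experiments and fixtures are deterministic under a fixed seed", {
  sc <- preset_scenario("AF_like_bacteriocin")
  sc$observation$n_bio <- 2L; sc$observation$n_tech <- 2L
  e1 <- run_experiment(sc, seed = 3, communities = c("full", "drop_B.ca"))
  e2 <- run_experiment(sc, seed = 3, communities = c("full", "drop_B.ca"))
  expect_identical(e1$abundance$entries, e2$abundance$entries)
  expect_identical(e1$ph, e2$ph)
  e3 <- run_experiment(sc, seed = 4, communities = c("full", "drop_B.ca"))
  expect_false(identical(e1$abundance$entries$value,
                         e3$abundance$entries$value))
})

test_that("fixture bundles are byte-identical for the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sc_files <- function(d) sort(list.files(d, full.names = TRUE))
  make_fixture("neutral", seed = 11, dir = d1)
  make_fixture("neutral", seed = 11, dir = d2)
  f1 <- sc_files(d1); f2 <- sc_files(d2)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) expect_identical(readLines(f1[i]), readLines(f2[i]))

  fx <- read_fixture(d1)
  expect_s3_class(fx$abundance, "abundance_table")
  expect_equal(nrow(fx$abundance$samples), 13 * 9)
})
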