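# Feature filtering, consumption/production calls and profile dissimilarity.

toy_features <- function(intensities, roles, env = "AF", community = NULL) {
  n <- nrow(intensities)
  feature_matrix(intensities,
                 data.frame(sample_id = rownames(intensities) %||%
                              paste0("m", seq_len(n)),
                            role = roles, environment = env,
                            community = community %||%
                              ifelse(roles == "fresh_medium", "fresh", "full"),
                            stringsAsFactors = FALSE))
}

test_that("NA-fraction filter uses a strict 80% threshold", {
  m <- matrix(1, nrow = 10, ncol = 3,
              dimnames = list(paste0("m", 1:10), c("f_drop", "f_keep", "f_ok")))
  m[1:9, "f_drop"] <- NA   # 90% missing -> dropped
  m[1:8, "f_keep"] <- NA   # exactly 80% -> retained
  fm <- toy_features(m, c(rep("community_spent", 8), rep("fresh_medium", 2)))
  filt <- filter_features(fm)
  expect_identical(colnames(filt$intensities), c("f_keep", "f_ok"))
  expect_identical(attr(filt, "dropped"), "f_drop")
})

test_that("a 30-feature fixture with 7 over-threshold features keeps 23", {
  set.seed(8)
  m <- matrix(rlnorm(10 * 30), 10, 30,
              dimnames = list(paste0("m", 1:10), paste0("f", 1:30)))
  over <- sample(30, 7)
  for (j in over) m[sample(10, 9), j] <- NA
  fm <- toy_features(m, c(rep("community_spent", 7), rep("fresh_medium", 3)))
  filt <- filter_features(fm)
  expect_equal(ncol(filt$intensities), 23L)
  expect_setequal(attr(filt, "dropped"), paste0("f", over))
})

test_that("spent-vs-fresh calls recover planted consumption and production", {
  set.seed(19)
  base <- 1e6
  m <- rbind(
    spent = matrix(c(base * 0.01, base * 20, base) *
                     rlnorm(9, 0, 0.01), 3, 3, byrow = TRUE),
    fresh = matrix(base * rlnorm(9, 0, 0.01), 3, 3))
  colnames(m) <- c("consumed_f", "produced_f", "stable_f")
  rownames(m) <- paste0("m", 1:6)
  fm <- toy_features(m, rep(c("community_spent", "fresh_medium"), each = 3))
  calls <- call_consumption_production(fm, "AF")
  expect_equal(calls$call[calls$feature == "consumed_f"], "consumed")
  expect_equal(calls$call[calls$feature == "produced_f"], "produced")
  expect_equal(calls$call[calls$feature == "stable_f"], "unchanged")
  expect_equal(calls$p_adjusted, p.adjust(calls$p_raw, "BH"))

  # identical constant groups: unchanged with p = 1
  m2 <- matrix(5, 4, 1, dimnames = list(paste0("m", 1:4), "flat"))
  fm2 <- toy_features(m2, rep(c("community_spent", "fresh_medium"), each = 2))
  c2 <- call_consumption_production(fm2, "AF")
  expect_equal(c2$call, "unchanged")
  expect_equal(c2$p_raw, 1)

  expect_error(call_consumption_production(fm, "APF"), "APF")
})

test_that("filtering commutes with calling on the retained features", {
  set.seed(23)
  m <- matrix(rlnorm(8 * 12), 8, 12,
              dimnames = list(paste0("m", 1:8), paste0("f", 1:12)))
  m[1:8, 1] <- c(NA, NA, NA, NA, NA, NA, NA, 1) # 87.5% NA -> dropped
  fm <- toy_features(m, c(rep("community_spent", 4), rep("fresh_medium", 4)))
  a <- call_consumption_production(filter_features(fm), "AF")
  b <- call_consumption_production(fm, "AF")
  b <- b[b$feature %in% a$feature, ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("log-mode calls are invariant to global rescaling", {
  set.seed(29)
  m <- matrix(rlnorm(12 * 6, log(1e5), 0.3), 12, 6,
              dimnames = list(paste0("m", 1:12), paste0("f", 1:6)))
  m[1:6, 2] <- m[1:6, 2] * 0.05
  fm <- toy_features(m, c(rep("community_spent", 6), rep("fresh_medium", 6)))
  fm_scaled <- fm
  fm_scaled$intensities <- fm$intensities * 1000
  a <- call_consumption_production(fm, "AF", log_mode = TRUE)
  b <- call_consumption_production(fm_scaled, "AF", log_mode = TRUE)
  expect_identical(a$call, b$call)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("profile dissimilarity flags a planted divergent profile", {
  set.seed(37)
  base <- rlnorm(8, log(1e5), 0.2)
  m <- t(replicate(10, base * rlnorm(8, 0, 0.05)))
  m[4, 1:3] <- m[4, 1:3] * 100
  rownames(m) <- paste0("m", 1:10)
  colnames(m) <- paste0("f", 1:8)
  fm <- toy_features(m, c(rep("community_spent", 8), rep("fresh_medium", 2)))
  pd <- profile_dissimilarity(fm, groups = rep("g", 10))
  expect_true(pd$outliers[4])
  expect_equal(sum(pd$outliers), 1L)

  # duplicated profiles are at distance zero
  m2 <- rbind(m, m[1, , drop = FALSE])
  rownames(m2)[11] <- "dup"
  expect_equal(as.matrix(bray_curtis(m2))["m1", "dup"], 0)
})

test_that("generated metabolite tables encode membership-dependent calls", {
  fm <- make_metabolite_matrix(c("full", "drop_E.fa", "drop_B.ca"),
                               c("AF", "APF"), seed = 4)
  filt <- filter_features(fm)
  expect_true(all(grepl("^rare_", attr(filt, "dropped"))))
  # arginine depleted only when the producer strain is present
  for (cm in c("full", "drop_B.ca")) {
    calls <- call_consumption_production(filt, "AF", community = cm)
    expect_equal(calls$call[calls$feature == "arginine"], "consumed")
  }
  calls_efa <- call_consumption_production(filt, "AF", community = "drop_E.fa")
  expect_equal(calls_efa$call[calls_efa$feature == "arginine"], "unchanged")
  # inulin fermentation acids appear only with the degrader, only in APF
  calls_apf <- call_consumption_production(filt, "APF", community = "full")
  expect_equal(calls_apf$call[calls_apf$feature == "succinate"], "produced")
  calls_apf_bca <- call_consumption_production(filt, "APF",
                                               community = "drop_B.ca")
  expect_equal(calls_apf_bca$call[calls_apf_bca$feature == "succinate"],
               "unchanged")
  calls_af <- call_consumption_production(filt, "AF", community = "full")
  expect_equal(calls_af$call[calls_af$feature == "succinate"], "unchanged")
})
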