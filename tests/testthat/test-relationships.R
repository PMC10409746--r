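# r_abs, relationship classification, the Wilcoxon shift test, keystone
# impact and delta-pH.

test_that("r_abs is the median dropout-to-full ratio", {
  expect_equal(compute_r_abs(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compute_r_abs(rep(4e7, 5), rep(8e7, 5)), 0.5)
  expect_true(is.na(compute_r_abs(c(1, 2), c(0, 0, 0))))
  expect_error(compute_r_abs(numeric(0), 1), "non-empty")
  # mean-based variant behind the flag
  expect_equal(compute_r_abs(c(0, 3), c(1, 1), use_mean = TRUE), 1.5)
})

test_that("detection-limit rules classify relationships in order", {
  det <- rep(FALSE, 9); cen <- rep(TRUE, 9)
  hi <- rep(1e6, 9); lo <- rep(0, 9)
  expect_equal(classify_relationship(lo, lo, cen, cen)$category, "below_DTL")
  expect_equal(classify_relationship(hi, lo, det, cen)$category, "exclusion")
  expect_equal(classify_relationship(lo, hi, cen, det)$category,
               "positive_dependency")
  expect_equal(classify_relationship(hi * 2, hi, det, det)$category, "negative")
  expect_equal(classify_relationship(hi / 2, hi, det, det)$category, "positive")
  tie <- classify_relationship(hi, hi, det, det)
  expect_equal(tie$category, "positive")
  expect_match(tie$note, "neutral")
  # "detected" needs strictly more than half the replicates
  half <- c(rep(TRUE, 5), rep(FALSE, 4))  # 4/9 detected
  most <- c(rep(FALSE, 5), rep(TRUE, 4))  # 5/9 detected
  v <- c(rep(0, 5), rep(1e6, 4))
  expect_equal(classify_relationship(v, lo, half, cen)$category, "below_DTL")
  expect_equal(classify_relationship(rev(v), lo, most, cen)$category,
               "exclusion")
})

test_that("Wilcoxon shift test matches full enumeration on separated groups", {
  x <- 1:9; y <- 101:109
  # oracle: enumerate all 48620 assignments of 9 labels among 18 values
  pool <- c(x, y)
  obs <- sum(rank(pool)[1:9])
  combos <- utils::combn(18, 9)
  stat <- colSums(matrix(rank(pool)[combos], nrow = 9))
  p_oracle <- mean(abs(stat - sum(1:18) / 2) >= abs(obs - sum(1:18) / 2))
  expect_equal(p_oracle, 2 / choose(18, 9))
  expect_equal(test_abundance_shift(x, y), p_oracle, tolerance = 1e-12)
  # symmetry and degenerate input
  expect_equal(test_abundance_shift(x, y), test_abundance_shift(y, x))
  expect_equal(test_abundance_shift(rep(5, 9), rep(5, 9)), 1)
  expect_error(test_abundance_shift(1:2, 1:9), ">= 3 replicates")
})

test_that("relationship matrix covers all ordered pairs with BH per family", {
  roster <- omm12_roster()
  set.seed(21)
  vals <- function(cm, s) rlnorm(1, log(1e7), 0.1)
  at <- build_abundance(roster, c("full", paste0("drop_", roster$strain_id)),
                        environment = "AF", n_rep = 9, value_fun = vals)
  at2 <- build_abundance(roster, c("full", paste0("drop_", roster$strain_id)),
                         environment = "APF", n_rep = 9, value_fun = vals)
  at$entries <- rbind(at$entries, at2$entries)
  at$samples <- rbind(at$samples, at2$samples)
  rel <- relationship_matrix(at)
  expect_equal(nrow(rel), 12 * 11 * 2)
  expect_true(all(table(rel$focal_x, rel$environment) == 11))
  # BH within each (focal, environment) family
  fam <- rel[rel$focal_x == "B.ca" & rel$environment == "AF", ]
  expect_equal(fam$p_adjusted, p.adjust(fam$p_raw, "BH"))
  # classification is exhaustive and exclusive
  expect_true(all(rel$category %in% c("negative", "positive", "exclusion",
                                      "positive_dependency", "below_DTL")))
  # missing full-consortium reference is a named error
  at_bad <- at
  keep <- !(at_bad$samples$community == "full" &
              at_bad$samples$environment == "APF")
  at_bad$samples <- at_bad$samples[keep, ]
  at_bad$entries <- at_bad$entries[at_bad$entries$sample_id %in%
                                     at_bad$samples$sample_id, ]
  expect_error(relationship_matrix(at_bad), "APF")
})

test_that("categories, p-values and r_abs are scale invariant", {
  roster <- toy_roster(4, dtl = 100)
  set.seed(33)
  at <- build_abundance(roster, c("full", "drop_S1"), n_rep = 9,
                        value_fun = function(cm, s) {
                          if (cm != "full" && s == "S2") rlnorm(1, log(4e4), 0.2)
                          else rlnorm(1, log(1e4), 0.2)
                        })
  rel1 <- relationship_matrix(at)
  at_scaled <- at
  at_scaled$entries$value <- at$entries$value * 137
  at_scaled$roster$dtl <- at$roster$dtl * 137
  rel2 <- relationship_matrix(at_scaled)
  expect_identical(rel1$category, rel2$category)
  expect_equal(rel1$p_raw, rel2$p_raw)
  expect_equal(rel1$r_abs, rel2$r_abs)
})

test_that("keystone impact counts Wilcoxon hits and detection categories", {
  rel <- data.frame(
    focal_x = "X", environment = "AF",
    affected_y = c("a", "b", "c", "d", "e"),
    r_abs = c(2, 0.5, NA, NA, 1),
    category = c("negative", "positive", "exclusion", "below_DTL", "positive"),
    p_raw = c(0.01, 0.2, 0.3, 1, 0.9),
    p_adjusted = c(0.05, 0.5, 0.6, 1, 1),
    significant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ki <- keystone_impact(rel, alpha = 0.05)
  expect_equal(ki$n_affected, 2L)            # a (p) + c (exclusion)
  expect_equal(ki$n_affected_wilcoxon, 1L)
  expect_setequal(strsplit(ki$affected_set, ",")[[1]], c("a", "c"))
  # impact is monotone in alpha
  ki50 <- keystone_impact(rel, alpha = 0.5)
  expect_gte(ki50$n_affected, ki$n_affected)
})

test_that("a same-distribution dropout yields near-nominal false positives", {
  set.seed(77)
  hits <- 0L; total <- 0L
  true_abund <- rlnorm(11, log(1e7), 1)
  for (i in 1:100) {
    g <- simulate_null_groups(true_abund, n_rep = 9, noise_sdlog = 0.2)
    p <- groupwise_shift_pvalues(g)
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  rate <- hits / total
  # exact test at N = 9: attainable size just below alpha
  expect_lt(rate, 0.07)
  expect_gt(rate, 0.02)
})

test_that("delta-pH is spent minus fresh, summarized by medians", {
  expect_equal(delta_ph(data.frame(ph_spent = 7, ph_fresh = 7))$delta_ph, 0)
  expect_equal(delta_ph(data.frame(ph_spent = 5.5, ph_fresh = 7))$delta_ph,
               -1.5)
  expect_error(delta_ph(data.frame(ph_spent = -1, ph_fresh = 7)), "ph_spent")
  ph <- data.frame(community = rep(c("full", "drop_E.fa"), each = 3),
                   environment = "AF",
                   ph_spent = c(6.1, 6.0, 6.2, 5.8, 5.9, 5.7),
                   ph_fresh = 7.0)
  s <- summarize_delta_ph(ph)
  expect_equal(s$median_delta_ph[s$community == "full"], -0.9)
  expect_equal(s$median_delta_ph[s$community == "drop_E.fa"], -1.2)
  expect_equal(s$n, c(3L, 3L))
})
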