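# Bray-Curtis, PCoA, confidence ellipses and PERMANOVA.

test_that("Bray-Curtis matches hand-computed values and bounds", {
  m <- rbind(a = c(6, 0, 2), b = c(2, 4, 0), c = c(6, 0, 2))
  bc <- as.matrix(bray_curtis(m))
  expect_equal(bc["a", "b"], 1 - 2 * 2 / 14, tolerance = 1e-12) # 0.714286
  expect_equal(bc["a", "c"], 0)
  disj <- rbind(u = c(1, 0), v = c(0, 3))
  expect_equal(as.vector(bray_curtis(disj)), 1)
  expect_error(bray_curtis(rbind(x = c(0, 0), y = c(1, 1))), "x")
  expect_error(bray_curtis(rbind(x = c(-1, 2), y = c(1, 1))), "non-negative")
  set.seed(2)
  r <- matrix(rlnorm(60), 6)
  b <- as.matrix(bray_curtis(r))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(b, t(b))
  expect_equal(diag(b), rep(0, 6), ignore_attr = TRUE)
})

test_that("PCoA embeds distances and is equivariant to row permutation", {
  # two samples at distance d -> one axis, coordinates +/- d/2
  d <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("s1", "s2"), NULL))
  p <- pcoa(d)
  expect_equal(ncol(p$coords), 1L)
  expect_equal(sort(unname(p$coords[, 1])), c(-0.3, 0.3))

  # points on a line: the embedding must reproduce all pairwise distances
  x <- c(0, 1, 2, 5)
  dm <- as.matrix(dist(x))
  p2 <- pcoa(dm)
  rec <- as.matrix(dist(p2$coords))
  expect_lt(max(abs(rec - dm)), 1e-9)
  expect_true(all(diff(p2$eigenvalues) <= 1e-9)) # sorted decreasing

  set.seed(4)
  m <- matrix(rlnorm(50), 10)
  rownames(m) <- paste0("s", 1:10)
  bc <- bray_curtis(m)
  perm <- sample(10)
  bc_p <- as.dist(as.matrix(bc)[perm, perm])
  c1 <- pcoa(bc)$coords
  c2 <- pcoa(bc_p)$coords
  expect_equal(c2, c1[perm, , drop = FALSE], tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("confidence ellipses flag samples beyond the chi-square quantile", {
  set.seed(9)
  base <- matrix(rnorm(20), 10)
  coords <- rbind(base, colMeans(base))   # last point at its group centroid
  groups <- rep("g", 11)
  ce <- confidence_ellipse_outliers(coords, groups)
  expect_false(ce$outliers[11])
  expect_equal(ce$ellipses$g$quantile, qchisq(0.95, 2))

  far <- rbind(matrix(rnorm(18, sd = 0.1), 9), c(50, 50))
  ce2 <- confidence_ellipse_outliers(far, rep("g", 10))
  expect_true(ce2$outliers[10])

  expect_error(confidence_ellipse_outliers(matrix(0, 2, 2), c("a", "a")),
               "fewer than 3")
  degen <- cbind(1:6, 2 * (1:6)) # rank-1 covariance
  expect_warning(confidence_ellipse_outliers(degen, rep("g", 6)), "singular")
})

test_that("ellipse outlier rate calibrates to 1 - level on Gaussian groups", {
  set.seed(123)
  n <- 10000
  coords <- matrix(rnorm(2 * n), ncol = 2)
  ce <- confidence_ellipse_outliers(coords, rep("g", n), level = 0.95)
  expect_lt(abs(mean(ce$outliers) - 0.05), 0.01)
})

test_that("PERMANOVA agrees with vegan and with exhaustive enumeration", {
  set.seed(31)
  m <- matrix(rlnorm(7 * 4, log(10), 0.8), nrow = 7)
  rownames(m) <- paste0("s", 1:7)
  groups <- c("a", "a", "a", "b", "b", "b", "b")
  bc <- bray_curtis(m)
  mine <- permanova(bc, groups, n_perm = 999, seed = 5)
  ref <- vegan::adonis2(bc ~ g, data = data.frame(g = groups),
                        permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  # 5-sample instance: p matches brute-force label enumeration.
  # Oracle route: Gower-centered inner-product matrix, SSW from projector
  # trace, enumerating all 120 orderings.
  m5 <- m[1:5, ]
  g5 <- c("a", "a", "b", "b", "b")
  bc5 <- as.matrix(bray_curtis(m5))
  oracle_f <- function(lab) {
    A <- -0.5 * bc5^2
    G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
    X <- model.matrix(~ lab)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    ssa <- sum(diag(H %*% G))
    sst <- sum(diag(G))
    (ssa / 1) / ((sst - ssa) / 3)
  }
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- as.matrix(perms[apply(perms, 1, function(r) !anyDuplicated(r)), ])
  f_all <- apply(perms, 1, function(p) oracle_f(factor(g5[p])))
  f_obs <- oracle_f(factor(g5))
  p_oracle <- mean(f_all >= f_obs - 1e-12)
  mine5 <- permanova(bc5, g5, exhaustive = TRUE)
  expect_equal(mine5$pseudo_F, f_obs, tolerance = 1e-10)
  expect_equal(mine5$p_value, p_oracle, tolerance = 1e-12)
})

test_that("PERMANOVA p is minimal for huge separation and order invariant", {
  set.seed(41)
  m <- rbind(matrix(rlnorm(15, log(10), 0.05), 5),
             matrix(rlnorm(15, log(10000), 0.05), 5))
  rownames(m) <- paste0("s", 1:10)
  groups <- rep(c("a", "b"), each = 5)
  bc <- bray_curtis(m)
  r <- permanova(bc, groups, n_perm = 199, seed = 1)
  # only permutations reproducing the two-cluster partition can reach F_obs
  expect_lte(r$p_value, 3 / 200)
  expect_gte(r$p_value, 1 / 200)
  # exhaustive small instance: exactly the partition-preserving orderings tie
  sep <- rbind(matrix(rlnorm(6, log(10), 0.01), 2),
               matrix(rlnorm(9, log(1e4), 0.01), 3))
  rownames(sep) <- paste0("t", 1:5)
  rex <- permanova(bray_curtis(sep), c("a", "a", "b", "b", "b"),
                   exhaustive = TRUE)
  expect_equal(rex$p_value, factorial(2) * factorial(3) / factorial(5))
  # relabeling group names and permuting samples changes nothing
  r2 <- permanova(bc, c(a = "grp1", b = "grp2")[groups], n_perm = 199, seed = 1)
  perm <- sample(10)
  r3 <- permanova(as.matrix(bc)[perm, perm], groups[perm],
                  n_perm = 199, seed = 1)
  expect_equal(r3$pseudo_F, r$pseudo_F)
  expect_equal(r3$p_value, r$p_value)
  expect_equal(r2$pseudo_F, r$pseudo_F)
  expect_error(permanova(bc, c(rep("a", 9), "b")), "single sample")

  pw <- pairwise_permanova(bc, c(rep("a", 3), rep("b", 3), rep("c", 4)),
                           n_perm = 99, seed = 2)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, "BH"))
})

test_that("community ordination flags a planted divergent community", {
  roster <- toy_roster(10, dtl = 0)
  set.seed(55)
  communities <- c("full", paste0("drop_S", 1:9))
  at <- build_abundance(roster, communities, n_rep = 3,
                        value_fun = function(cm, s) {
                          shift <- 4 * (cm == "drop_S2" && s == "S10")
                          rlnorm(1, log(1e3) + shift, 0.05)
                        })
  ord <- ordinate_communities(at, aggregate = "median_community",
                              n_perm = 0, seed = 3)
  expect_equal(nrow(ord$pcoa$coords), 10L)
  flagged <- names(ord$outliers)[ord$outliers]
  expect_true("drop_S2@AF" %in% flagged)
  expect_lte(length(flagged), 2L)
})
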