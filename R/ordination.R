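# Community-structure analysis: Bray-Curtis dissimilarity on absolute
# abundances, principal coordinates, per-group 95% confidence ellipses with
# outlier flagging, and one-way PERMANOVA with a pairwise BH-adjusted mode.
#
# Bray-Curtis uses vegan::vegdist, the same routine the field uses on
# absolute abundance matrices. PERMANOVA implements the within/between
# sums-of-squared-dissimilarities pseudo-F directly so that the permutation
# policy is fully specified (seeded substreams per comparison, exhaustive
# enumeration on small instances); vegan::adonis2 serves as an independent
# cross-check in the test suite.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = 1 - 2 * sum(min(u, v)) / sum(u + v)` on non-negative profiles;
#' censored abundances enter as 0.
#'
#' @param profiles numeric matrix, samples in rows, strains/features in
#'   columns, or an `abundance_table`.
#' @return a `dist` object.
#' @export
bray_curtis <- function(profiles) {
  if (inherits(profiles, "abundance_table")) profiles <- as.matrix(profiles)
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stopf("Bray-Curtis requires non-negative profiles")
  zero <- rowSums(profiles) == 0
  if (any(zero)) {
    stopf("all-zero profile for sample(s): %s",
          paste(rownames(profiles)[zero] %||% which(zero), collapse = ", "))
  }
  vegan::vegdist(profiles, method = "bray")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling (double-centering + eigendecomposition). Axes are
#' ordered by eigenvalue; negative eigenvalues are retained in the report but
#' excluded from coordinates and explained-variance fractions. The sign of
#' each axis is fixed by making its largest-magnitude coordinate positive.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param k number of axes to return (default: all positive-eigenvalue axes).
#' @return list of class `pcoa_result`: `coords` (samples x axes),
#'   `eigenvalues` (all, including negative), `var_explained` (fractions of
#'   the positive-eigenvalue total).
#' @export
pcoa <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      stopf("pcoa needs a symmetric dissimilarity matrix")
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  keep <- if (is.null(k)) pos else pos[seq_len(min(k, length(pos)))]
  coords <- fit$points[, keep, drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coords = coords, eigenvalues = eig,
                 var_explained = eig[keep] / sum(eig[pos])),
            class = "pcoa_result")
}

#' Per-group confidence ellipses and outlier flags on the ordination plane
#'
#' For each group, a bivariate-normal ellipse is taken from the sample mean
#' and covariance of the first two ordination axes at the chi-square (2 df)
#' quantile of `level`. A sample is flagged as an outlier when its squared
#' Mahalanobis distance to its own group's center exceeds that quantile.
#' Singular group covariances are ridge-regularized (eps = 1e-9 * trace)
#' with a warning.
#'
#' @param coords numeric matrix with at least two columns (axes 1-2 used).
#' @param groups group label per row; each group needs >= 3 samples.
#' @param level confidence level (default 0.95).
#' @return list with `ellipses` (per group: `center`, `cov`, `quantile`,
#'   `level`) and `outliers` (named logical per sample).
#' @export
confidence_ellipse_outliers <- function(coords, groups, level = 0.95) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  stopifnot(nrow(coords) == length(groups))
  q <- stats::qchisq(level, df = 2)
  ell <- list()
  out <- stats::setNames(logical(nrow(coords)),
                         rownames(coords) %||% seq_len(nrow(coords)))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) stopf("group '%s' has fewer than 3 samples", g)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    S <- stats::cov(coords[idx, , drop = FALSE])
    if (abs(det(S)) < .Machine$double.eps * sum(diag(S))^2) {
      warnf("singular covariance in group '%s'; ridge added", g)
      S <- S + diag(1e-9 * sum(diag(S)), 2)
    }
    d2 <- stats::mahalanobis(coords[idx, , drop = FALSE], ctr, S)
    out[idx] <- d2 > q
    ell[[g]] <- list(center = ctr, cov = S, quantile = q, level = level)
  }
  list(ellipses = ell, outliers = out)
}

# Anderson (2001) one-way decomposition from a dissimilarity matrix: total
# and within-group sums of squared dissimilarities, pseudo-F and R2.
permanova_decompose <- function(d2, groups) {
  n <- nrow(d2)
  k <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssa <- sst - ssw
  list(F = (ssa / (k - 1)) / (ssw / (n - k)), R2 = ssa / sst)
}

pseudo_f <- function(dm, groups) permanova_decompose(dm^2, groups)$F

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Pseudo-F from within- and between-group sums of squared dissimilarities,
#' with p-value `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` over random label
#' permutations (the observed labeling always counts once). When
#' `exhaustive = TRUE` all `n!` label orders are enumerated instead and the
#' p-value is the exact fraction of orders with `F >= F_obs`. Samples are
#' put into canonical (label-sorted, then name-sorted) order before
#' permuting, so the result is invariant to input ordering; the permutation
#' stream is a named substream of `seed`.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups group label per sample; >= 2 groups with >= 2 samples each.
#' @param n_perm number of random permutations (default 9999).
#' @param seed master seed for the permutation stream.
#' @param exhaustive enumerate all label permutations (feasible for ~8
#'   samples or fewer).
#' @return data.frame with `pseudo_F`, `R2`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1, exhaustive = FALSE) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(dm) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stopf("PERMANOVA needs >= 2 groups")
  if (any(tab < 2)) {
    stopf("group(s) with a single sample: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  }
  ord <- order(groups, rownames(dm) %||% seq_along(groups))
  dm <- dm[ord, ord, drop = FALSE]
  groups <- groups[ord]
  n <- length(groups)
  d2 <- dm^2
  obs <- permanova_decompose(d2, groups)
  f_obs <- obs$F
  r2 <- obs$R2
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1L, function(p) permanova_decompose(d2, groups[p])$F)
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    lab <- paste(sort(unique(groups)), collapse = "|")
    f_perm <- with_substream(seed, paste0("permanova:", lab), {
      vapply(seq_len(n_perm),
             function(i) permanova_decompose(d2, groups[sample(n)])$F,
             numeric(1))
    })
    p_val <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  data.frame(pseudo_F = f_obs, R2 = r2, p_value = p_val, n_perm = n_used)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs [permanova()] on every pair of groups; each comparison draws its
#' permutations from a substream derived from the pair's label, so results
#' do not depend on evaluation order.
#'
#' @inheritParams permanova
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed = 1) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  res <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    idx <- groups %in% c(gs[i], gs[j])
    r <- permanova(dm[idx, idx, drop = FALSE], groups[idx],
                   n_perm = n_perm, seed = seed)
    res[[paste(gs[i], gs[j])]] <- cbind(
      data.frame(group_a = gs[i], group_b = gs[j]), r)
  }
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Full community-structure ordination of an abundance table
#'
#' Bray-Curtis on absolute abundances (optionally log10(x + dtl)-transformed
#' or aggregated to per-community medians), PCoA, per-environment confidence
#' ellipses with outlier flags, and PERMANOVA across environments.
#'
#' @param at an `abundance_table`.
#' @param aggregate `"sample"` (every well its own point) or
#'   `"median_community"` (median profile per community x environment, the
#'   representation used for dropout-panel ordinations).
#' @param transform `"none"` (raw absolute abundances, the default
#'   convention) or `"log10_dtl"` for `log10(x + dtl)`.
#' @param level confidence level for the ellipses.
#' @param n_perm,seed PERMANOVA settings.
#' @return list of class `community_ordination`: `bc`, `pcoa`, `ellipses`,
#'   `outliers`, `permanova`, `pairwise`, `meta`.
#' @export
ordinate_communities <- function(at, aggregate = c("sample", "median_community"),
                                 transform = c("none", "log10_dtl"),
                                 level = 0.95, n_perm = 999, seed = 1) {
  aggregate <- match.arg(aggregate)
  transform <- match.arg(transform)
  m <- as.matrix(at)
  meta <- at$samples
  if (aggregate == "median_community") {
    key <- paste(meta$community, meta$environment, sep = "@")
    mm <- apply(m, 2, function(col) tapply(col, key, stats::median))
    m <- as.matrix(mm)
    parts <- strsplit(rownames(m), "@", fixed = TRUE)
    meta <- data.frame(sample_id = rownames(m),
                       community = vapply(parts, `[`, "", 1L),
                       environment = vapply(parts, `[`, "", 2L),
                       stringsAsFactors = FALSE)
  }
  if (transform == "log10_dtl") {
    dtl <- at$roster$dtl[match(colnames(m), at$roster$strain_id)]
    dtl[is.na(dtl) | dtl <= 0] <- 1
    m <- sweep(m, 2, dtl, function(x, d) log10(x + d))
  }
  bc <- bray_curtis(m)
  pc <- pcoa(bc)
  ce <- confidence_ellipse_outliers(pc$coords, meta$environment, level = level)
  n_env <- length(unique(meta$environment))
  pm <- if (n_env >= 2 && n_perm >= 1) {
    permanova(bc, meta$environment, n_perm = n_perm, seed = seed)
  } else {
    data.frame(pseudo_F = NA_real_, R2 = NA_real_, p_value = NA_real_,
               n_perm = 0L)
  }
  pw <- if (n_env > 2 && n_perm >= 1) {
    pairwise_permanova(bc, meta$environment, n_perm = n_perm, seed = seed)
  } else NULL
  structure(list(bc = bc, pcoa = pc, ellipses = ce$ellipses,
                 outliers = ce$outliers, permanova = pm, pairwise = pw,
                 meta = meta),
            class = "community_ordination")
}

#' @export
print.community_ordination <- function(x, ...) {
  cat(sprintf("community ordination: %d points, %d flagged outlier(s)\n",
              nrow(x$pcoa$coords), sum(x$outliers)))
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$permanova$pseudo_F, x$permanova$R2, x$permanova$p_value,
              x$permanova$n_perm))
  invisible(x)
}
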