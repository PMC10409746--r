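# Downstream statistics on untargeted metabolite feature tables: NA-fraction
# filtering, spent-vs-fresh comparison with consumption/production calls, and
# Bray-Curtis profile dissimilarity.
#
# A feature matrix is a list:
#   intensities  samples x features numeric matrix, NA = feature not detected
#   samples      data.frame(sample_id, role in {community_spent, fresh_medium},
#                environment, community)
# Missing intensities are treated as "not detected": they are imputed as 0
# only for dissimilarity analysis, never for the t-tests (which use observed
# values only).

#' Construct a feature matrix
#'
#' @param intensities samples x features matrix (non-negative, NA allowed);
#'   rownames are sample ids.
#' @param samples data.frame with `sample_id`, `role`
#'   (`"community_spent"` or `"fresh_medium"`), `environment`, `community`.
#' @param annotation optional named character vector feature -> metabolite.
#' @return list of class `feature_matrix`.
#' @export
feature_matrix <- function(intensities, samples, annotation = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(samples))
  if (is.null(rownames(intensities))) rownames(intensities) <- samples$sample_id
  bad <- setdiff(unique(samples$role), c("community_spent", "fresh_medium"))
  if (length(bad)) stopf("unknown sample role(s): %s", paste(bad, collapse = ", "))
  for (env in unique(samples$environment)) {
    if (!any(samples$role == "fresh_medium" & samples$environment == env)) {
      stopf("no fresh-medium reference samples for environment '%s'", env)
    }
  }
  if (any(intensities < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  structure(list(intensities = intensities, samples = samples,
                 annotation = annotation),
            class = "feature_matrix")
}

#' Drop features with too many missing values
#'
#' Features whose NA fraction across all analyzed samples is strictly greater
#' than `max_na_frac` are removed.
#'
#' @param fm a `feature_matrix`.
#' @param max_na_frac maximum tolerated NA fraction (default 0.8).
#' @return the filtered `feature_matrix`, with the dropped feature ids in
#'   attribute `"dropped"`.
#' @export
filter_features <- function(fm, max_na_frac = 0.8) {
  stopifnot(inherits(fm, "feature_matrix"))
  na_frac <- colMeans(is.na(fm$intensities))
  drop <- na_frac > max_na_frac
  out <- fm
  out$intensities <- fm$intensities[, !drop, drop = FALSE]
  if (!is.null(fm$annotation)) {
    out$annotation <- fm$annotation[intersect(names(fm$annotation),
                                              colnames(out$intensities))]
  }
  attr(out, "dropped") <- colnames(fm$intensities)[drop]
  out
}

# Welch two-sided t-test on observed values; degenerate inputs (identical
# constants, too few observations) fall back to p = 1 / no call.
welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Call metabolite consumption and production against fresh medium
#'
#' Per feature and environment, a two-sided Welch t-test compares spent
#' community supernatants with the fresh-medium references (on observed
#' values only). A feature is *consumed* when the shift is significant and
#' the spent mean is below the fresh mean, *produced* when significant and
#' above, *unchanged* otherwise. With `log_mode = TRUE` the test runs on
#' log-transformed intensities, which makes the calls invariant to global
#' multiplicative rescaling (variance-stabilized mode).
#'
#' @param fm a `feature_matrix` (filter first; see [filter_features()]).
#' @param environment environment to analyze.
#' @param community optionally restrict the spent samples to one community
#'   label (default: all spent samples of the environment).
#' @param alpha significance level (default 0.05).
#' @param log_mode test log-transformed intensities (default FALSE).
#' @return data.frame with `feature`, `call`, `p_raw`, `p_adjusted`
#'   (BH, reported alongside; calls use raw p), `mean_spent`, `mean_fresh`.
#' @export
call_consumption_production <- function(fm, environment, community = NULL,
                                        alpha = 0.05, log_mode = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  s <- fm$samples
  spent <- s$role == "community_spent" & s$environment == environment
  if (!is.null(community)) spent <- spent & s$community == community
  fresh <- s$role == "fresh_medium" & s$environment == environment
  if (sum(spent) < 2 || sum(fresh) < 2) {
    stopf("need >= 2 spent and >= 2 fresh replicates in environment '%s'",
          environment)
  }
  x <- fm$intensities
  if (log_mode) x <- log(x)
  res <- lapply(colnames(x), function(f) {
    a <- x[spent, f]; b <- x[fresh, f]
    p <- welch_p(a, b)
    ma <- mean(fm$intensities[spent, f], na.rm = TRUE)
    mb <- mean(fm$intensities[fresh, f], na.rm = TRUE)
    call <- if (is.na(p) || p >= alpha || isTRUE(all.equal(ma, mb))) "unchanged"
            else if (ma < mb) "consumed" else "produced"
    data.frame(feature = f, call = call, p_raw = p, p_adjusted = NA_real_,
               mean_spent = ma, mean_fresh = mb, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res
}

#' Bray-Curtis ordination of metabolite profiles
#'
#' Imputes missing intensities as 0 (not detected) and delegates to
#' [bray_curtis()], [pcoa()] and [confidence_ellipse_outliers()] with the
#' same contracts as the community-structure module. Groups default to the
#' environment label.
#'
#' @param fm a `feature_matrix` (already filtered).
#' @param groups optional grouping for the ellipses (default: environment).
#' @param level ellipse confidence level.
#' @return list with `bc`, `pcoa`, `ellipses`, `outliers`.
#' @export
profile_dissimilarity <- function(fm, groups = NULL, level = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- fm$intensities
  m[is.na(m)] <- 0
  bc <- bray_curtis(m)
  pc <- pcoa(bc)
  groups <- groups %||% fm$samples$environment
  ce <- confidence_ellipse_outliers(pc$coords, groups, level = level)
  list(bc = bc, pcoa = pc, ellipses = ce$ellipses, outliers = ce$outliers)
}
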