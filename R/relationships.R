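# The core dropout statistic: r_abs, detection-limit relationship categories,
# Wilcoxon significance, keystone impact and delta-pH.
#
# r_abs is the ratio of a strain y's absolute abundance in the dropout
# community lacking strain x to its abundance in the full consortium,
# aggregated as the median over replicates. r_abs > 1 marks a negative
# relationship of x toward y (y rises when x is removed), r_abs < 1 a
# positive one. Detection-limit logic overrides the ratio: a strain detected
# only in the dropout is an exclusion, one detected only in the full
# consortium a positive dependency, and one never detected anywhere stays
# below_DTL.

REL_CATEGORIES <- c("negative", "positive", "exclusion",
                    "positive_dependency", "below_DTL")

#' Compute the dropout-to-full abundance ratio r_abs
#'
#' @param y_dropout replicate abundances of strain y in the dropout community
#'   (censored entries as 0).
#' @param y_full replicate abundances of y in the full consortium.
#' @param use_mean aggregate with the arithmetic mean instead of the median.
#' @return `median(y_dropout) / median(y_full)`, or `NA` when the denominator
#'   is 0 (classification then falls to the detection-limit rules).
#' @export
compute_r_abs <- function(y_dropout, y_full, use_mean = FALSE) {
  if (!length(y_dropout) || !length(y_full)) {
    stopf("replicate vectors must be non-empty")
  }
  agg <- if (use_mean) mean else stats::median
  den <- agg(y_full)
  if (den == 0) return(NA_real_)
  agg(y_dropout) / den
}

#' Classify a strain relationship from dropout vs. full abundances
#'
#' Detection policy: a group counts as *detected* when strictly more than 50%
#' of its replicates lie above the detection limit, and as *never detected*
#' when no replicate does. Rules, in order: both never detected -> below_DTL;
#' never in full but detected in dropout -> exclusion; never in dropout but
#' detected in full -> positive_dependency; otherwise r_abs > 1 -> negative
#' and r_abs <= 1 -> positive (a ratio of exactly 1 is broken toward the
#' weaker claim and annotated as neutral).
#'
#' @param y_dropout,y_full replicate abundances (censored as 0).
#' @param censored_dropout,censored_full logical censoring flags per replicate.
#' @param use_mean see [compute_r_abs()].
#' @return list with `category`, `r_abs` and `note`.
#' @export
classify_relationship <- function(y_dropout, y_full,
                                  censored_dropout, censored_full,
                                  use_mean = FALSE) {
  stopifnot(length(y_dropout) == length(censored_dropout),
            length(y_full) == length(censored_full))
  if (!length(y_dropout) || !length(y_full)) {
    stopf("replicate vectors must be non-empty")
  }
  detected <- function(cens) mean(!cens) > 0.5
  never <- function(cens) all(cens)
  r <- compute_r_abs(y_dropout, y_full, use_mean = use_mean)
  nd <- never(censored_dropout); nf <- never(censored_full)
  dd <- detected(censored_dropout); df <- detected(censored_full)
  if (nd && nf) return(list(category = "below_DTL", r_abs = NA_real_, note = ""))
  if (nf && dd) return(list(category = "exclusion", r_abs = NA_real_, note = ""))
  if (nd && df) return(list(category = "positive_dependency", r_abs = NA_real_,
                            note = ""))
  if (is.na(r)) {
    # denominator median 0 without a clean detection call
    if (stats::median(y_dropout) > 0) {
      return(list(category = "negative", r_abs = NA_real_,
                  note = "full-consortium median 0; ratio undefined"))
    }
    return(list(category = "below_DTL", r_abs = NA_real_,
                note = "both medians 0 with sporadic detection"))
  }
  if (r > 1) return(list(category = "negative", r_abs = r, note = ""))
  note <- if (r == 1) "r_abs exactly 1; neutral" else ""
  list(category = "positive", r_abs = r, note = note)
}

#' Two-sided Wilcoxon rank-sum test for a dropout-induced abundance shift
#'
#' Uses the exact null distribution when both groups have at most 12
#' replicates and the pooled values are tie-free; otherwise the normal
#' approximation with continuity correction. Two groups of identical
#' constant values return p = 1.
#'
#' @param y_dropout,y_full replicate abundances (>= 3 each).
#' @return two-sided p-value.
#' @export
test_abundance_shift <- function(y_dropout, y_full) {
  if (length(y_dropout) < 3 || length(y_full) < 3) {
    stopf("test_abundance_shift needs >= 3 replicates per group (got %d and %d)",
          length(y_dropout), length(y_full))
  }
  pooled <- c(y_dropout, y_full)
  if (length(unique(pooled)) == 1L) return(1)
  use_exact <- length(y_dropout) <= 12 && length(y_full) <= 12 &&
    !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(y_dropout, y_full, exact = use_exact,
                       correct = TRUE)$p.value)
}

group_values <- function(e, community, environment, strain) {
  sel <- e$community == community & e$environment == environment &
    e$strain_id == strain
  list(value = e$value[sel], censored = e$censored[sel])
}

#' Relationship table across all dropout runs and environments
#'
#' One record per ordered (focal strain x, affected strain y, environment)
#' with y != x, comparing the dropout community lacking x against the same
#' environment's full consortium. Benjamini-Hochberg adjustment is applied
#' within each (x, environment) family; `significant` flags raw p < alpha
#' (the per-strain convention used for dropout panels), orthogonal to the
#' category call.
#'
#' @param at an `abundance_table` containing the full consortium and one or
#'   more `drop_<strain>` communities per environment.
#' @param alpha significance level (default 0.05).
#' @param use_mean aggregate abundances with the mean instead of the median.
#' @return data.frame with columns `focal_x`, `affected_y`, `environment`,
#'   `r_abs`, `category`, `p_raw`, `p_adjusted`, `significant`, `note`.
#' @export
relationship_matrix <- function(at, alpha = 0.05, use_mean = FALSE) {
  stopifnot(inherits(at, "abundance_table"))
  e <- merge(at$entries, at$samples, by = "sample_id")
  envs <- unique(e$environment)
  out <- list()
  for (env in envs) {
    in_env <- e[e$environment == env, ]
    if (!any(in_env$community == "full")) {
      stopf("no full-consortium reference measured in environment '%s'", env)
    }
    drops <- setdiff(unique(in_env$community), "full")
    for (cm in drops) {
      x <- sub("^drop_", "", cm)
      fam <- list()
      for (y in setdiff(at$roster$strain_id, x)) {
        g_drop <- group_values(in_env, cm, env, y)
        g_full <- group_values(in_env, "full", env, y)
        if (!length(g_drop$value) || !length(g_full$value)) next
        cl <- classify_relationship(g_drop$value, g_full$value,
                                    g_drop$censored, g_full$censored,
                                    use_mean = use_mean)
        p <- test_abundance_shift(g_drop$value, g_full$value)
        fam[[y]] <- data.frame(
          focal_x = x, affected_y = y, environment = env,
          r_abs = cl$r_abs, category = cl$category,
          p_raw = p, p_adjusted = NA_real_,
          significant = p < alpha, note = cl$note,
          stringsAsFactors = FALSE)
      }
      fam <- do.call(rbind, fam)
      if (!is.null(fam)) {
        fam$p_adjusted <- stats::p.adjust(fam$p_raw, method = "BH")
        out[[paste(env, cm)]] <- fam
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keystone impact per (dropout strain, environment)
#'
#' Counts the community members significantly affected by a strain's removal.
#' The headline count (`n_affected`) combines raw-p Wilcoxon significance
#' with the detection-limit categories (exclusion, positive dependency);
#' the Wilcoxon-only and BH-adjusted variants are reported alongside because
#' the two multiple-testing conventions coexist in dropout studies.
#'
#' @param rel relationship table from [relationship_matrix()].
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (focal_x, environment):
#'   `n_affected`, `n_affected_wilcoxon`, `n_affected_wilcoxon_bh`,
#'   `affected_set` (comma-joined strain ids for the headline count).
#' @export
keystone_impact <- function(rel, alpha = 0.05) {
  detect_cat <- rel$category %in% c("exclusion", "positive_dependency")
  rel$hit_total <- rel$p_raw < alpha | detect_cat
  rel$hit_wilcoxon <- rel$p_raw < alpha
  rel$hit_bh <- rel$p_adjusted < alpha
  key <- rel[c("focal_x", "environment")]
  agg <- stats::aggregate(rel[c("hit_total", "hit_wilcoxon", "hit_bh")],
                          key, sum)
  names(agg) <- c("focal_x", "environment", "n_affected",
                  "n_affected_wilcoxon", "n_affected_wilcoxon_bh")
  sets <- stats::aggregate(list(affected_set = rel$affected_y),
                           cbind(key, hit = rel$hit_total),
                           function(s) paste(s, collapse = ","))
  sets <- sets[sets$hit, c("focal_x", "environment", "affected_set")]
  out <- merge(agg, sets, by = c("focal_x", "environment"), all.x = TRUE)
  out$affected_set[is.na(out$affected_set)] <- ""
  out[order(out$environment, -out$n_affected), ]
}

#' Environmental modification: delta-pH of spent culture supernatants
#'
#' delta-pH = pH of the spent culture supernatant minus pH of the fresh
#' medium; negative values mean acidification by the community.
#'
#' @param ph data.frame with columns `ph_spent`, `ph_fresh` and (for
#'   summaries) `community`, `environment`.
#' @return the input with a `delta_ph` column appended.
#' @export
delta_ph <- function(ph) {
  for (col in c("ph_spent", "ph_fresh")) {
    if (!col %in% names(ph)) stopf("pH table is missing column '%s'", col)
    v <- ph[[col]]
    if (any(v <= 0 | v >= 14)) stopf("%s outside (0, 14)", col)
  }
  ph$delta_ph <- ph$ph_spent - ph$ph_fresh
  ph
}

#' Median delta-pH per community and environment
#'
#' @param ph data.frame accepted by [delta_ph()] with `community` and
#'   `environment` columns.
#' @return data.frame with `community`, `environment`, `median_delta_ph`, `n`.
#' @export
summarize_delta_ph <- function(ph) {
  ph <- delta_ph(ph)
  agg <- stats::aggregate(list(median_delta_ph = ph$delta_ph),
                          ph[c("community", "environment")], stats::median)
  n <- stats::aggregate(list(n = ph$delta_ph),
                        ph[c("community", "environment")], length)
  merge(agg, n, by = c("community", "environment"))
}
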