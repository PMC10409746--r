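# Host-side readouts from the gnotobiotic-mouse arm: composite cecal
# histopathology score and the cecal-to-body-weight ratio.

#' Composite cecal histopathology score
#'
#' Sums four sub-scores -- submucosal edema (0-3), PMN infiltration (0-4),
#' goblet-cell loss (0-3) and epithelial damage (0-3) -- into a total of
#' 0-13, banded as 0-3 no inflammation, 4-8 mild inflammation, 9-13 profound
#' inflammation.
#'
#' @param edema integer 0-3.
#' @param pmn_infiltration integer 0-4.
#' @param goblet_loss integer 0-3.
#' @param epithelial_damage integer 0-3.
#' @return data.frame with `total` and `category` (vectorized).
#' @export
pathology_score <- function(edema, pmn_infiltration, goblet_loss,
                            epithelial_damage) {
  check <- function(x, lo, hi, name) {
    if (any(x != round(x) | x < lo | x > hi)) {
      stopf("%s must be an integer in [%d, %d]", name, lo, hi)
    }
  }
  check(edema, 0L, 3L, "edema")
  check(pmn_infiltration, 0L, 4L, "pmn_infiltration")
  check(goblet_loss, 0L, 3L, "goblet_loss")
  check(epithelial_damage, 0L, 3L, "epithelial_damage")
  total <- edema + pmn_infiltration + goblet_loss + epithelial_damage
  category <- cut(total, breaks = c(-1, 3, 8, 13),
                  labels = c("no inflammation", "mild inflammation",
                             "profound inflammation"))
  data.frame(total = as.integer(total), category = as.character(category),
             stringsAsFactors = FALSE)
}

#' Cecal-to-body-weight ratio
#'
#' @param cecal_weight cecal weight in g (> 0).
#' @param body_weight mouse body weight in g (> 0).
#' @return dimensionless ratio (vectorized).
#' @export
cecal_ratio <- function(cecal_weight, body_weight) {
  if (any(cecal_weight <= 0)) stopf("cecal_weight must be > 0")
  if (any(body_weight <= 0)) stopf("body_weight must be > 0")
  cecal_weight / body_weight
}

#' Two-sided Welch t-test for host readout group comparisons
#'
#' Shared test used for delta-pH, host scores and metabolite features.
#'
#' @param a,b numeric vectors (>= 2 observations each).
#' @return two-sided p-value.
#' @export
compare_groups_t <- function(a, b) {
  p <- welch_p(a, b)
  if (is.na(p)) stopf("need >= 2 observations per group")
  p
}
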