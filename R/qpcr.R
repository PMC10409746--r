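# qPCR normalization chain: raw strain-specific readouts (16S copies per 5 ng
# gDNA template) to absolute abundances (genome equivalents per ml or g), and
# its inverse, the observation model used by the simulator.
#
# The normalization multiplies the readout by the total extracted gDNA over
# the template mass (gdna_conc * elution_volume / template_mass), divides by
# the strain's 16S copies per genome and by the sample amount. This is the
# only dimensionally consistent composition of the four named factors that
# yields copies per ml (or per g). Dividing by n_16S reports genome
# equivalents; set `genome_equivalents = FALSE` to report 16S copies instead.
#
# Detection-limit censoring acts on the *raw* copies-per-template scale: a
# readout below the strain's DTL is flagged censored and reported as 0. A
# readout exactly at the DTL counts as detected.

#' Normalize a qPCR readout to absolute abundance
#'
#' @param copies_per_template 16S copies per `template_mass` ng of gDNA
#'   template (non-negative; vectorized).
#' @param gdna_conc gDNA concentration of the extract, ng/ul.
#' @param elution_volume elution volume of the extract, ul (default 150).
#' @param template_mass template mass per reaction, ng (default 5).
#' @param n_16S strain-specific 16S rRNA gene copies per genome.
#' @param sample_amount sample volume (ml) or mass (g), > 0.
#' @param dtl strain-specific detection limit on the copies-per-template
#'   scale (default 0 = no censoring).
#' @param genome_equivalents divide by `n_16S` (default TRUE); otherwise the
#'   result is normalized 16S copies per ml or g.
#' @return data.frame with columns `value` (absolute abundance; 0 when
#'   censored) and `censored`.
#' @export
normalize_qpcr <- function(copies_per_template, gdna_conc,
                           elution_volume = 150, template_mass = 5,
                           n_16S = 1L, sample_amount = 1,
                           dtl = 0, genome_equivalents = TRUE) {
  if (any(copies_per_template < 0)) stopf("copies_per_template must be >= 0")
  if (any(gdna_conc < 0)) stopf("gdna_conc must be >= 0")
  if (any(elution_volume <= 0)) stopf("elution_volume must be > 0")
  if (any(template_mass <= 0)) stopf("template_mass must be > 0")
  if (any(sample_amount <= 0)) stopf("sample_amount must be > 0")
  copy_div <- if (genome_equivalents) n_16S else 1
  value <- copies_per_template * (gdna_conc * elution_volume / template_mass) /
    copy_div / sample_amount
  censored <- copies_per_template < dtl
  value[censored] <- 0
  data.frame(value = value, censored = censored)
}

#' Simulate a raw qPCR readout from a true abundance
#'
#' Inverse of [normalize_qpcr()]: converts a true absolute abundance back to
#' the copies-per-template scale and optionally applies multiplicative
#' lognormal measurement noise. With noise disabled,
#' `normalize_qpcr(simulate_readout(a)) == a` to machine precision.
#'
#' @param abundance true absolute abundance (genome equivalents per ml or g).
#' @param gdna_conc,elution_volume,template_mass,n_16S,sample_amount as in
#'   [normalize_qpcr()].
#' @param noise_sdlog sdlog of the lognormal measurement noise (0 = off).
#'   Draws use the current RNG state; seed upstream.
#' @return numeric vector of copies per template.
#' @export
simulate_readout <- function(abundance, gdna_conc = 20, elution_volume = 150,
                             template_mass = 5, n_16S = 1L, sample_amount = 1,
                             noise_sdlog = 0) {
  if (any(abundance < 0)) stopf("abundance must be >= 0")
  copies <- abundance * n_16S * sample_amount /
    (gdna_conc * elution_volume / template_mass)
  if (noise_sdlog > 0) {
    copies <- copies * stats::rlnorm(length(copies), 0, noise_sdlog)
  }
  copies
}

#' Normalize a table of raw qPCR readouts into an abundance table
#'
#' @param readouts data.frame with columns `sample_id`, `strain_id`,
#'   `copies_per_template`, `gdna_conc` and optionally `elution_volume`,
#'   `template_mass` (defaults 150 ul / 5 ng).
#' @param roster a `strain_roster` supplying `n_16S` and `dtl` per strain.
#' @param samples sample metadata (see [abundance_table()]); `amount` is the
#'   per-sample volume/mass used in the normalization.
#' @param genome_equivalents see [normalize_qpcr()].
#' @return an `abundance_table`.
#' @export
normalize_readouts <- function(readouts, roster, samples,
                               genome_equivalents = TRUE) {
  for (col in c("sample_id", "strain_id", "copies_per_template", "gdna_conc")) {
    if (!col %in% names(readouts)) stopf("readouts is missing column '%s'", col)
  }
  idx <- match(readouts$strain_id, roster$strain_id)
  if (anyNA(idx)) {
    stopf("readouts reference strains not in the roster: %s",
          paste(unique(readouts$strain_id[is.na(idx)]), collapse = ", "))
  }
  amt <- samples$amount[match(readouts$sample_id, samples$sample_id)]
  if (anyNA(amt)) stopf("readouts reference samples without metadata")
  norm <- normalize_qpcr(
    readouts$copies_per_template,
    gdna_conc = readouts$gdna_conc,
    elution_volume = readouts$elution_volume %||% 150,
    template_mass = readouts$template_mass %||% 5,
    n_16S = roster$n_16S[idx],
    sample_amount = amt,
    dtl = roster$dtl[idx],
    genome_equivalents = genome_equivalents)
  abundance_table(
    data.frame(sample_id = readouts$sample_id, strain_id = readouts$strain_id,
               value = norm$value, censored = norm$censored,
               stringsAsFactors = FALSE),
    samples, roster)
}
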