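# The central data container (detection-limit-censored absolute abundances)
# and readers/writers for the tabular formats the pipeline touches.
#
# On-disk canonical form is long (tidy): one row per (sample, strain) with the
# sample metadata inline. Delimiter is auto-detected from the extension
# (.csv -> comma, .tsv/.txt -> tab). Floats are serialized with 17 significant
# digits so that write -> read -> write is the identity on text.

delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Construct an abundance table
#'
#' @param entries data.frame with columns `sample_id`, `strain_id`, `value`
#'   (absolute abundance, normalized 16S copies per ml or per g) and
#'   `censored` (TRUE when the raw readout fell below the strain's detection
#'   limit). Censored entries hold value 0 for arithmetic; the flag is
#'   authoritative for detection logic.
#' @param samples data.frame with columns `sample_id`, `community`
#'   (`"full"` or `"drop_<strain>"`), `environment`, `bio_replicate`,
#'   `tech_replicate`, `amount`.
#' @param roster the `strain_roster` the samples were assayed against.
#' @return list of class `abundance_table`.
#' @export
abundance_table <- function(entries, samples, roster) {
  req <- c("sample_id", "strain_id", "value", "censored")
  miss <- setdiff(req, names(entries))
  if (length(miss)) stopf("entries is missing column(s): %s",
                          paste(miss, collapse = ", "))
  reqs <- c("sample_id", "community", "environment",
            "bio_replicate", "tech_replicate", "amount")
  misss <- setdiff(reqs, names(samples))
  if (length(misss)) stopf("samples is missing column(s): %s",
                           paste(misss, collapse = ", "))
  if (any(entries$value < 0)) {
    stopf("negative abundance at entry row %s",
          paste(which(entries$value < 0), collapse = ", "))
  }
  if (any(samples$amount <= 0)) stopf("sample amount must be > 0")
  key <- interaction(samples$community, samples$environment,
                     samples$bio_replicate, samples$tech_replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stopf("duplicate (community, environment, bio_replicate, tech_replicate) in samples")
  }
  entries$value[entries$censored] <- 0
  structure(list(entries = entries, samples = samples, roster = roster),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "abundance table: %d entries, %d samples, %d strains, %d censored (%.1f%%)\n",
    nrow(x$entries), nrow(x$samples), length(unique(x$entries$strain_id)),
    sum(x$entries$censored), 100 * mean(x$entries$censored)))
  invisible(x)
}

#' Wide sample-by-strain abundance matrix
#'
#' Censored entries contribute 0, which is what Bray-Curtis ordination on
#' detection-limit-censored data expects.
#'
#' @param x an `abundance_table`.
#' @param ... unused.
#' @return numeric matrix, rows = samples, columns = strains.
#' @export
as.matrix.abundance_table <- function(x, ...) {
  strains <- intersect(x$roster$strain_id, unique(x$entries$strain_id))
  samples <- x$samples$sample_id
  m <- matrix(0, nrow = length(samples), ncol = length(strains),
              dimnames = list(samples, strains))
  e <- x$entries[x$entries$strain_id %in% strains, ]
  m[cbind(match(e$sample_id, samples), match(e$strain_id, strains))] <- e$value
  m
}

#' Average technical replicates into biological replicates
#'
#' Arithmetic mean of the abundance values over `tech_replicate` within each
#' (community, environment, bio_replicate, strain). The result is flagged
#' censored only when every contributing well was censored.
#'
#' @param x an `abundance_table`.
#' @return an `abundance_table` with one sample per biological replicate.
#' @export
aggregate_bio_replicates <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  e <- merge(x$entries, x$samples, by = "sample_id")
  key <- c("community", "environment", "bio_replicate", "strain_id")
  agg <- stats::aggregate(e[c("value", "censored")], e[key],
                          function(v) if (is.logical(v)) all(v) else mean(v))
  agg$censored <- as.logical(agg$censored)
  agg$sample_id <- with(agg, paste(community, environment, bio_replicate, sep = "_"))
  samples <- unique(agg[c("sample_id", "community", "environment", "bio_replicate")])
  samples$tech_replicate <- 1L
  amt <- stats::aggregate(list(amount = e$amount),
                          e[c("community", "environment", "bio_replicate")], mean)
  samples <- merge(samples, amt, by = c("community", "environment", "bio_replicate"))
  abundance_table(agg[c("sample_id", "strain_id", "value", "censored")],
                  samples[c("sample_id", "community", "environment",
                            "bio_replicate", "tech_replicate", "amount")],
                  x$roster)
}

#' Read a long-format abundance table
#'
#' Required columns: `sample_id`, `strain_id`, `value`; sample metadata
#' (`community`, `environment`, `bio_replicate`, `tech_replicate`, `amount`)
#' may be inline or supplied through `samples`. Values below the strain's
#' detection limit are flagged censored (a value exactly at the limit counts
#' as detected); a pre-existing `censored` column takes precedence. Rows
#' referencing strains absent from the roster are kept and flagged in the
#' `contaminant` column, with a warning.
#'
#' @param path delimited text file (.csv or .tsv).
#' @param roster a `strain_roster`.
#' @param samples optional sample metadata data.frame (see
#'   [abundance_table()]); required when not inline in the file.
#' @param dtl_map optional named numeric vector mapping strain_id to the
#'   detection limit *on the scale of the stored values*; defaults to the
#'   roster's `dtl` column.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, roster, samples = NULL, dtl_map = NULL) {
  d <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
  for (col in c("sample_id", "strain_id", "value")) {
    if (!col %in% names(d)) stopf("abundance file is missing column '%s'", col)
  }
  if (any(d$value < 0)) {
    stopf("negative abundance value at file row %s",
          paste(which(d$value < 0), collapse = ", "))
  }
  unknown <- setdiff(unique(d$strain_id), roster$strain_id)
  d$contaminant <- d$strain_id %in% unknown
  if (length(unknown)) {
    warnf("abundance file references %d strain(s) not in the roster (flagged as contaminant): %s",
          length(unknown), paste(unknown, collapse = ", "))
  }
  if (!"censored" %in% names(d)) {
    dtl_map <- dtl_map %||% stats::setNames(roster$dtl, roster$strain_id)
    lim <- dtl_map[d$strain_id]
    lim[is.na(lim)] <- 0
    d$censored <- d$value < lim
  } else {
    d$censored <- as.logical(d$censored)
  }
  meta_cols <- c("community", "environment", "bio_replicate",
                 "tech_replicate", "amount")
  if (is.null(samples)) {
    if (!all(meta_cols %in% names(d))) {
      stopf("abundance file has no inline sample metadata; supply 'samples'")
    }
    samples <- unique(d[c("sample_id", meta_cols)])
  }
  at <- abundance_table(d[c("sample_id", "strain_id", "value", "censored")],
                        samples, roster)
  at$entries$contaminant <- d$contaminant
  at
}

#' Write an abundance table (long format, metadata inline)
#'
#' @param x an `abundance_table`.
#' @param path output .csv or .tsv path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  d <- merge(x$entries, x$samples, by = "sample_id", sort = FALSE)
  ord <- order(d$sample_id, d$strain_id)
  d <- d[ord, c("sample_id", "strain_id", "value", "censored",
                "community", "environment", "bio_replicate",
                "tech_replicate", "amount")]
  d$value <- format_full(d$value)
  d$amount <- format_full(d$amount)
  utils::write.table(d, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

rel_cols <- c("focal_x", "affected_y", "environment", "r_abs", "category",
              "p_raw", "p_adjusted", "significant")

#' Write a strain-relationship table
#'
#' One row per (focal strain x, affected strain y, environment) with the
#' r_abs ratio, the relationship category, raw and BH-adjusted Wilcoxon p
#' and the significance flag. Round-trips losslessly through
#' [read_relationship_table()].
#'
#' @param rel data.frame as produced by [relationship_matrix()].
#' @param path output .csv or .tsv path.
#' @return `path`, invisibly.
#' @export
write_relationship_table <- function(rel, path) {
  if (nrow(rel) == 0L) {
    rel <- as.data.frame(stats::setNames(rep(list(character(0)), length(rel_cols)),
                                         rel_cols))
  }
  miss <- setdiff(rel_cols, names(rel))
  if (length(miss)) stopf("relationship table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  out <- rel[rel_cols]
  for (col in c("r_abs", "p_raw", "p_adjusted")) out[[col]] <- format_full(out[[col]])
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a strain-relationship table written by [write_relationship_table()]
#'
#' @param path .csv or .tsv path.
#' @return data.frame with the relationship schema.
#' @export
read_relationship_table <- function(path) {
  d <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE,
                         colClasses = c(r_abs = "numeric", p_raw = "numeric",
                                        p_adjusted = "numeric",
                                        significant = "logical"))
  miss <- setdiff(rel_cols, names(d))
  if (length(miss)) stopf("relationship file is missing column(s): %s",
                          paste(miss, collapse = ", "))
  d
}
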