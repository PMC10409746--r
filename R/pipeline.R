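# Orchestration: run every analysis stage on a dropout experiment bundle and
# emit a reproducible report with a parameter-digest manifest.

#' Run the full dropout analysis chain
#'
#' Stages: (1) abundance QC (censoring counts), (2) strain-relationship
#' table, (3) keystone impact summary, (4) community ordination with
#' confidence ellipses, outliers and PERMANOVA, (5) delta-pH summary,
#' (6) metabolite consumption/production calls per environment, (7) manifest
#' (stage list, audit counts, seed and parameter digest). Stages whose
#' inputs are absent from the bundle (pH, metabolites) are skipped and noted
#' in the manifest.
#'
#' @param bundle a `dropout_experiment` (from [run_experiment()] /
#'   [make_fixture()]), a fixture directory path, or a list with elements
#'   `abundance` and optionally `ph`, `metabolites`.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param aggregate replicate level for the relationship statistics:
#'   `"well"` (all wells, the N = 9 convention) or `"bio"` (technical
#'   replicates averaged first).
#' @param ordination_aggregate point level for the ordination (see
#'   [ordinate_communities()]).
#' @param transform ordination transform (`"none"` or `"log10_dtl"`).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed master seed for permutation streams.
#' @param out_dir optional directory: write every stage output as CSV plus
#'   `manifest.json`.
#' @return list of class `dropout_report` with `abundance`, `relationships`,
#'   `keystones`, `ordination`, `delta_ph`, `metabolite_calls`, `manifest`.
#' @export
run_full_analysis <- function(bundle, alpha = 0.05,
                              aggregate = c("well", "bio"),
                              ordination_aggregate = "median_community",
                              transform = "none",
                              n_perm = 999, seed = 1, out_dir = NULL) {
  aggregate <- match.arg(aggregate)
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  if (is.character(bundle) && length(bundle) == 1L) bundle <- read_fixture(bundle)
  at <- bundle$abundance
  if (is.null(at)) stopf("bundle has no abundance table")
  stages <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages[[length(stages) + 1L]] <<- name
    res
  }
  at_stat <- run_stage("abundance",
    if (aggregate == "bio") aggregate_bio_replicates(at) else at)
  relationships <- run_stage("relationships",
                             relationship_matrix(at_stat, alpha = alpha))
  keystones <- run_stage("keystones", keystone_impact(relationships, alpha = alpha))
  ordination <- run_stage("ordination",
    ordinate_communities(at, aggregate = ordination_aggregate,
                         transform = transform, n_perm = n_perm, seed = seed))
  dph <- if (!is.null(bundle$ph)) {
    run_stage("delta_ph", summarize_delta_ph(bundle$ph))
  }
  met <- if (!is.null(bundle$metabolites)) {
    run_stage("metabolites", {
      fm <- filter_features(bundle$metabolites)
      calls <- lapply(unique(fm$samples$environment), function(env) {
        cbind(environment = env,
              call_consumption_production(fm, env, alpha = alpha))
      })
      list(calls = do.call(rbind, calls),
           dropped_features = attr(fm, "dropped"))
    })
  }
  censored_n <- sum(at$entries$censored)
  params <- list(alpha = alpha, aggregate = aggregate,
                 ordination_aggregate = ordination_aggregate,
                 transform = transform, n_perm = n_perm, seed = seed)
  stages <- c(stages, "manifest")
  manifest <- list(
    package_version = as.character(utils::packageVersion("ommdropout")),
    stages = stages,
    seed = seed,
    parameters = params,
    counts = list(samples = nrow(at$samples),
                  entries = nrow(at$entries),
                  censored_entries = censored_n,
                  relationships = nrow(relationships),
                  flagged_outliers = sum(ordination$outliers),
                  dropped_features = length(met$dropped_features %||% character())),
    parameter_digest = param_digest(params))
  report <- structure(
    list(abundance = at, relationships = relationships, keystones = keystones,
         ordination = ordination, delta_ph = dph,
         metabolite_calls = met$calls, manifest = manifest),
    class = "dropout_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Stable digest of the parameter set: md5 of its canonical JSON rendering.
param_digest <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(params[order(names(params))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a dropout report to disk
#'
#' @param report a `dropout_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_relationship_table(report$relationships,
                           file.path(dir, "relationships.csv"))
  utils::write.csv(report$keystones, file.path(dir, "keystones.csv"),
                   row.names = FALSE)
  utils::write.csv(as.matrix(report$ordination$bc),
                   file.path(dir, "bray_curtis.csv"))
  utils::write.csv(data.frame(sample_id = rownames(report$ordination$pcoa$coords),
                              report$ordination$pcoa$coords,
                              outlier = report$ordination$outliers),
                   file.path(dir, "pcoa_coordinates.csv"), row.names = FALSE)
  utils::write.csv(report$ordination$permanova,
                   file.path(dir, "permanova.csv"), row.names = FALSE)
  if (!is.null(report$ordination$pairwise)) {
    utils::write.csv(report$ordination$pairwise,
                     file.path(dir, "permanova_pairwise.csv"), row.names = FALSE)
  }
  if (!is.null(report$delta_ph)) {
    utils::write.csv(report$delta_ph, file.path(dir, "delta_ph.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$metabolite_calls)) {
    utils::write.csv(report$metabolite_calls,
                     file.path(dir, "metabolite_calls.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.dropout_report <- function(x, ...) {
  cat("dropout analysis report\n")
  cat(sprintf("  stages: %s\n", paste(x$manifest$stages, collapse = ", ")))
  cat(sprintf("  %d relationships, %d censored entries, %d ordination outlier(s)\n",
              x$manifest$counts$relationships,
              x$manifest$counts$censored_entries,
              x$manifest$counts$flagged_outliers))
  invisible(x)
}
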