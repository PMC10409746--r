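# On-disk fixture bundles and the metabolite proxy generator.
#
# The metabolite generator emulates the downstream shape of an untargeted
# feature table (samples x features, lognormal intensities, missing values),
# with ground-truth consumption/production rules keyed to community
# membership: e.g. arginine and serine are depleted only by communities that
# contain the enterococcal strain; alanine and the inulin fermentation acids
# (succinate, propionate) are released only when the Bacteroides-like
# degrader is present in the polysaccharide-like environment.

default_metabolite_rules <- function() {
  list(
    list(feature = "arginine",   requires = "E.fa", env = NULL,  fold = 0.02),
    list(feature = "serine",     requires = "E.fa", env = NULL,  fold = 0.02),
    list(feature = "alanine",    requires = "B.ca", env = "APF", fold = 6),
    list(feature = "succinate",  requires = "B.ca", env = "APF", fold = 8),
    list(feature = "propionate", requires = "B.ca", env = "APF", fold = 8),
    list(feature = "lactate",    requires = "E.fa", env = NULL,  fold = 5))
}

#' Generate a synthetic metabolite feature table for a dropout experiment
#'
#' One spent-medium profile per (community, environment, biological
#' replicate) plus `n_fresh` fresh-medium references per environment.
#' Rule-governed features change by `fold` relative to fresh medium whenever
#' the required strain is in the community (and the environment matches);
#' generic features are unchanged. A block of rare features with >80%
#' missingness is appended to exercise the NA filter.
#'
#' @param communities character vector of community labels.
#' @param environments character vector of environment names.
#' @param seed master seed.
#' @param rules list of rules (see `default_metabolite_rules`).
#' @param n_generic number of unchanged generic features (default 20).
#' @param n_rare number of mostly-missing features (default 4).
#' @param n_rep spent replicates per community (default 3).
#' @param n_fresh fresh-medium references per environment (default 3).
#' @param noise_sdlog lognormal intensity noise (default 0.15).
#' @param na_frac random missingness among generic features (default 0.05).
#' @return a `feature_matrix` with ground-truth calls in attribute `"truth"`.
#' @export
make_metabolite_matrix <- function(communities, environments, seed = 1,
                                   rules = default_metabolite_rules(),
                                   n_generic = 20, n_rare = 4,
                                   n_rep = 3, n_fresh = 3,
                                   noise_sdlog = 0.15, na_frac = 0.05) {
  feat_rule <- vapply(rules, `[[`, "", "feature")
  features <- c(feat_rule, sprintf("feature_%02d", seq_len(n_generic)),
                sprintf("rare_%02d", seq_len(n_rare)))
  base <- with_substream(seed, "metabolite_base", {
    stats::setNames(stats::rlnorm(length(features), log(1e6), 0.5), features)
  })
  rows <- list(); meta <- list(); truth <- list()
  for (env in environments) {
    for (f in seq_len(n_fresh)) {
      sid <- paste("fresh", env, f, sep = "_")
      rows[[sid]] <- with_substream(seed, paste("met", sid), {
        base * stats::rlnorm(length(base), 0, noise_sdlog)
      })
      meta[[sid]] <- data.frame(sample_id = sid, role = "fresh_medium",
                                environment = env, community = "fresh",
                                stringsAsFactors = FALSE)
    }
    for (cm in communities) {
      dropped <- if (cm == "full") NULL else sub("^drop_", "", cm)
      fold <- stats::setNames(rep(1, length(features)), features)
      for (r in rules) {
        present <- !identical(dropped, r$requires)
        env_ok <- is.null(r$env) || identical(r$env, env)
        if (present && env_ok) fold[r$feature] <- r$fold
      }
      truth[[paste(env, cm)]] <- data.frame(
        environment = env, community = cm, feature = feat_rule,
        true_call = ifelse(fold[feat_rule] < 1, "consumed",
                           ifelse(fold[feat_rule] > 1, "produced", "unchanged")),
        stringsAsFactors = FALSE)
      for (b in seq_len(n_rep)) {
        sid <- paste("spent", env, cm, b, sep = "_")
        rows[[sid]] <- with_substream(seed, paste("met", sid), {
          base * fold * stats::rlnorm(length(base), 0, noise_sdlog)
        })
        meta[[sid]] <- data.frame(sample_id = sid, role = "community_spent",
                                  environment = env, community = cm,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  m <- with_substream(seed, "metabolite_missing", {
    gen <- grepl("^feature_", colnames(m))
    miss <- matrix(stats::runif(length(m)) < na_frac, nrow(m), ncol(m))
    miss[, !gen] <- FALSE
    rare <- grepl("^rare_", colnames(m))
    miss[, rare] <- matrix(stats::runif(nrow(m) * sum(rare)) < 0.9,
                           nrow(m), sum(rare))
    m[miss] <- NA
    m
  })
  fm <- feature_matrix(m, meta)
  attr(fm, "truth") <- do.call(rbind, truth)
  fm
}

#' Write a complete fixture bundle for a preset scenario
#'
#' Runs the dropout experiment, generates the metabolite proxy table, and
#' writes the CSV bundle (abundances with inline metadata, pH records,
#' metabolite intensities + sample roles, ground truth, roster config).
#' The same seed yields a byte-identical bundle.
#'
#' @param preset preset name (see [preset_scenario()]).
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return the `dropout_experiment` (with `$metabolites`), invisibly.
#' @export
make_fixture <- function(preset, seed, dir) {
  scenario <- preset_scenario(preset)
  exp <- run_experiment(scenario, seed = seed)
  envs <- names(scenario$environments)
  communities <- unique(exp$abundance$samples$community)
  exp$metabolites <- make_metabolite_matrix(communities, envs, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(exp$abundance, file.path(dir, "abundance.csv"))
  ph <- exp$ph
  ph$ph_spent <- format_full(ph$ph_spent)
  utils::write.table(ph, file.path(dir, "ph.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  mi <- exp$metabolites$intensities
  mdf <- data.frame(sample_id = rownames(mi),
                    apply(mi, 2, format_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mdf, file.path(dir, "metabolites.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(exp$metabolites$samples,
                     file.path(dir, "metabolite_samples.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  tr <- exp$truth
  tr$true_abundance <- format_full(tr$true_abundance)
  tr$true_delta_ph <- format_full(tr$true_delta_ph)
  utils::write.table(tr, file.path(dir, "ground_truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(preset = preset, seed = seed,
         strains = exp$abundance$roster),
    file.path(dir, "roster.json"), dataframe = "columns", auto_unbox = TRUE,
    digits = NA)
  invisible(exp)
}

#' Read a fixture bundle written by [make_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `abundance` (an `abundance_table`), `ph`,
#'   `metabolites` (a `feature_matrix`), `truth`, `roster`.
#' @export
read_fixture <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "roster.json"),
                             simplifyVector = TRUE)
  roster <- strain_roster(cfg$strains$strain_id, cfg$strains$full_name,
                          cfg$strains$n_16S, cfg$strains$dtl)
  at <- read_abundance_table(file.path(dir, "abundance.csv"), roster)
  ph <- utils::read.csv(file.path(dir, "ph.csv"), stringsAsFactors = FALSE)
  mi <- utils::read.csv(file.path(dir, "metabolites.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  rownames(mi) <- mi$sample_id
  mi <- as.matrix(mi[, -1, drop = FALSE])
  ms <- utils::read.csv(file.path(dir, "metabolite_samples.csv"),
                        stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  list(abundance = at, ph = ph, metabolites = feature_matrix(mi, ms),
       truth = truth, roster = roster)
}
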