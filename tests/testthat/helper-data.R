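# Shared builders for small in-memory fixtures.

toy_roster <- function(n = 3, dtl = 10) {
  strain_roster(paste0("S", seq_len(n)), n_16S = 5L, dtl = dtl)
}

# Abundance table for one environment: full consortium plus the given dropout
# communities, with per-(community, strain) values supplied as a function.
build_abundance <- function(roster, communities = "full", environment = "AF",
                            n_rep = 9, value_fun = function(cm, s) 1e6,
                            dtl_scale = 1) {
  entries <- list(); samples <- list()
  for (cm in communities) {
    dropped <- if (cm == "full") NULL else sub("^drop_", "", cm)
    members <- setdiff(roster$strain_id, dropped)
    for (r in seq_len(n_rep)) {
      sid <- paste(cm, environment, r, sep = "_")
      vals <- vapply(members, function(s) value_fun(cm, s), numeric(1))
      lim <- roster$dtl[match(members, roster$strain_id)] * dtl_scale
      entries[[sid]] <- data.frame(sample_id = sid, strain_id = members,
                                   value = vals, censored = vals < lim,
                                   stringsAsFactors = FALSE)
      samples[[sid]] <- data.frame(sample_id = sid, community = cm,
                                   environment = environment,
                                   bio_replicate = (r - 1) %/% 3 + 1,
                                   tech_replicate = (r - 1) %% 3 + 1,
                                   amount = 1, stringsAsFactors = FALSE)
    }
  }
  abundance_table(do.call(rbind, entries), do.call(rbind, samples), roster)
}

random_relationships <- function(n = 50) {
  cats <- c("negative", "positive", "exclusion", "positive_dependency",
            "below_DTL")
  p <- runif(n)
  data.frame(focal_x = sample(LETTERS, n, TRUE),
             affected_y = sample(letters, n, TRUE),
             environment = sample(c("AF", "APF"), n, TRUE),
             r_abs = ifelse(runif(n) < 0.2, NA, rlnorm(n)),
             category = sample(cats, n, TRUE),
             p_raw = p, p_adjusted = pmin(1, p * 2),
             significant = p < 0.05,
             stringsAsFactors = FALSE)
}
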