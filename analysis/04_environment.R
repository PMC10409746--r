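#!/usr/bin/env Rscript
# Environmental modification: delta-pH of the spent supernatants and
# metabolite consumption/production calls against fresh medium.

library(ommdropout)

fx <- read_fixture("results/fixture")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

dph <- summarize_delta_ph(fx$ph)
write.csv(dph, "results/tables/delta_ph.csv", row.names = FALSE)
key <- dph[(dph$community == "full") |
             (dph$community == "drop_E.fa" & dph$environment == "AF") |
             (dph$community == "drop_B.ca" & dph$environment == "APF"), ]
message("median delta-pH of the headline communities:")
print(key[order(key$environment, key$community), ], row.names = FALSE)

fm <- filter_features(fx$metabolites)
message(sprintf("metabolite features: %d kept, %d dropped (>80%% missing)",
                ncol(fm$intensities), length(attr(fm, "dropped"))))
calls <- do.call(rbind, lapply(c("AF", "APF"), function(env) {
  do.call(rbind, lapply(c("full", "drop_E.fa", "drop_B.ca"), function(cm) {
    cbind(environment = env, community = cm,
          call_consumption_production(fm, env, community = cm, alpha = 0.05))
  }))
}))
write.csv(calls, "results/tables/metabolite_calls.csv", row.names = FALSE)

aa <- calls[calls$feature %in% c("arginine", "serine", "alanine",
                                 "succinate", "propionate"), ]
changed <- aa[aa$call != "unchanged", c("environment", "community",
                                        "feature", "call")]
message("annotated metabolites with consumption/production calls:")
print(changed[order(changed$feature, changed$environment), ],
      row.names = FALSE)
message(paste("note: arginine/serine depletion tracks the presence of E.fa;",
              "succinate/propionate release requires B.ca in APF"))
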