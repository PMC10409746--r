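#!/usr/bin/env Rscript
# Community-structure ordination of the simulated dropout communities.
#
# Bray-Curtis dissimilarity on absolute abundances (median profile per
# community x medium), PCoA, 95% confidence ellipse per medium with outlier
# flagging, and PERMANOVA between the two media.

library(ommdropout)

fx <- read_fixture("results/fixture")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

ord <- ordinate_communities(fx$abundance, aggregate = "median_community",
                            transform = "none", n_perm = 9999, seed = 20230)
print(ord)

write.csv(as.matrix(ord$bc), "results/tables/bray_curtis.csv")
write.csv(data.frame(point = rownames(ord$pcoa$coords),
                     ord$pcoa$coords[, 1:2],
                     outlier = ord$outliers),
          "results/tables/pcoa_coordinates.csv", row.names = FALSE)
write.csv(ord$permanova, "results/tables/permanova.csv", row.names = FALSE)

flagged <- names(ord$outliers)[ord$outliers]
message("communities outside their medium's 95% confidence ellipse:")
message(paste(" ", flagged, collapse = "\n"))
message(sprintf(
  "PERMANOVA AF vs APF: pseudo-F = %.2f, R2 = %.2f, p = %.4g (9999 permutations)",
  ord$permanova$pseudo_F, ord$permanova$R2, ord$permanova$p_value))
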