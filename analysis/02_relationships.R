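#!/usr/bin/env Rscript
# Strain relationships and keystone impact from the simulated dropout data.
#
# Computes r_abs for every ordered (removed strain x, affected strain y,
# medium) triple, classifies the relationship with the detection-limit rules,
# tests the abundance shift (two-sided Wilcoxon on the 9 wells), and counts
# the species each removal significantly affected.

library(ommdropout)

fx <- read_fixture("results/fixture")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

rel <- relationship_matrix(fx$abundance, alpha = 0.05)
write_relationship_table(rel, "results/tables/relationships.csv")
message(sprintf("relationship table: %d (x, y, medium) records", nrow(rel)))

tab <- table(rel$category, rel$environment)
message("category counts per medium:")
print(tab)

ki <- keystone_impact(rel, alpha = 0.05)
write.csv(ki, "results/tables/keystones.csv", row.names = FALSE)
message("top keystone impacts (count of affected species per removal):")
print(head(ki[order(-ki$n_affected), ], 6), row.names = FALSE)

# relationships conserved across both media (same non-trivial category)
wide <- merge(rel[rel$environment == "AF", c("focal_x", "affected_y", "category")],
              rel[rel$environment == "APF", c("focal_x", "affected_y", "category")],
              by = c("focal_x", "affected_y"), suffixes = c("_AF", "_APF"))
conserved <- wide[wide$category_AF == wide$category_APF &
                    wide$category_AF != "below_DTL", ]
sig <- merge(conserved,
             aggregate(significant ~ focal_x + affected_y, rel, all))
conserved_sig <- sig[sig$significant, c("focal_x", "affected_y", "category_AF")]
write.csv(conserved_sig, "results/tables/conserved_relationships.csv",
          row.names = FALSE)
message(sprintf("relationships conserved across both media (significant): %d",
                nrow(conserved_sig)))
print(conserved_sig, row.names = FALSE)
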