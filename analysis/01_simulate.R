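#!/usr/bin/env Rscript
# Stage 1: simulate the monitoring campaign.
#
# Generates the default synthetic dataset: 16 sites in three pollution tiers
# (2 highly / 5 moderately / 9 less polluted), monthly samples over 15 years,
# built from a known 3-source structure (treatment-plant point source,
# agriculture/livestock, background/ionic) with monsoon dilution/enrichment,
# slow monotone trends and lognormal noise. Writes the long-format records,
# the ground-truth matrices and a manifest under results/synthetic/.
#
# Every later stage regenerates this dataset from the same seed instead of
# re-reading the files, so the whole workflow is reproducible from the seed
# alone.

library(riverwq)

seed <- 42L
d <- generate_dataset(generator_config(), seed = seed)
paths <- write_dataset(d, "results/synthetic", seed = seed)

cat("samples:", nrow(d$matrix$values), "\n")
cat("sites:", length(unique(d$matrix$meta$site_id)),
    " tiers:", paste(names(table(d$truth$tiers)),
                     table(d$truth$tiers), collapse = ", "), "\n")
cat("files:\n"); print(unname(paths))
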