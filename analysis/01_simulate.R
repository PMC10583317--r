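#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cryoconite study bundle.
# Writes the seven input tables as TSV plus an RDS snapshot (with the
# planted truth) that the later stages read.

library(cryonet)

seed <- as.integer(Sys.getenv("CRYONET_SEED", "1"))
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- sim_spec(rng_seed = seed)
bundle <- simulate_bundle(spec, out_dir = out)
saveRDS(bundle, file.path("results", "bundle.rds"))
saveRDS(spec, file.path("results", "sim_spec.rds"))

message(sprintf("bundle: %d taxa x %d samples, %d KOs, seed %d",
                nrow(bundle$sgb), ncol(bundle$sgb), nrow(bundle$ko), seed))
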