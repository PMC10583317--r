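#!/usr/bin/env Rscript
# Stage 5: LASSO selection of radiation-predictive modules and the
# standardized final model on the selected eigengenes.

library(cryonet)

seed <- as.integer(Sys.getenv("CRYONET_SEED", "1"))
bundle <- readRDS(file.path("results", "bundle.rds"))
net <- readRDS(file.path("results", "network.rds"))
cfg <- run_config(rng_seed = seed)

rad <- bundle$meteo$radiation[match(rownames(net$eigengenes),
                                    bundle$meteo$sample_id)]
cv <- cv_select_lambda(net$eigengenes, rad, cfg$k_folds,
                       seed = cryonet:::derive_seed(seed, 13L),
                       n_lambda = cfg$n_lambda,
                       lambda_min_ratio = cfg$lambda_min_ratio)
final <- standardized_final_model(
  net$eigengenes[, cv$selected, drop = FALSE], rad)
saveRDS(cv, file.path("results", "lasso.rds"))
saveRDS(final, file.path("results", "final_model.rds"))

write_results(list(cv_table = cv$cv_table,
                   final_model = final$coefficients),
              file.path("results", "05"))
message(sprintf("selected: %s | adjusted R^2 = %.3f",
                paste(cv$selected, collapse = ", "), final$adjusted_r2))
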