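# Stage 5: screen the covariates for multicollinearity, assemble the 1:1
# presence:pseudoabsence dataset (one trip per individual, one null per
# trip), compare the environmental candidate model against the
# distance-from-colony competitor, fit the binomial additive mixed model,
# and quantify run-to-run variability with the 40-replicate ensemble.

source("analysis/00_config.R")

matchup <- read.csv(file.path(OUT, "matchup.csv"))
matchup$date <- as.Date(matchup$date)

seeds <- split_seed(MASTER_SEED, 3)
tab <- assemble_dataset(matchup, seed = seeds[1])
cat(sprintf("modeling table: %d records, %d individuals, balanced %d:%d\n",
            nrow(tab), nlevels(tab$animal_id), sum(tab$presence == 1),
            sum(tab$presence == 0)))

gvif <- gvif_check(tab, COVARIATES)
write.csv(gvif, file.path(OUT, "gvif.csv"), row.names = FALSE)
cat("GVIF screening:", if (any(gvif$flagged))
  paste("flagged", paste(gvif$covariate[gvif$flagged], collapse = ", "))
  else "no covariate flagged", "\n")

sel <- select_model(CANDIDATES, tab)
write.csv(sel$ranking, file.path(OUT, "model_selection.csv"),
          row.names = FALSE)
cat(sprintf("selected candidate '%s' (AIC %.1f, AUC %.3f)%s\n", sel$best,
            sel$ranking$aic[1], sel$ranking$auc[1],
            if (sel$conflict) " [AIC/AUC rankings disagreed]" else ""))

fit <- fit_binomial_gamm(tab, CANDIDATES[[sel$best]])
print(fit)
jsonlite::write_json(
  list(covariates = fit$covariates, aic = fit$aic, auc = fit$auc,
       deviance_explained = fit$deviance_explained,
       re_variance = fit$re_variance, smooth_table = fit$smooth_table),
  file.path(OUT, "fit.json"), auto_unbox = TRUE, digits = 10)
pr <- do.call(rbind, lapply(names(fit$partial), function(v)
  cbind(covariate = v, fit$partial[[v]])))
write.csv(pr, file.path(OUT, "partial_response.csv"), row.names = FALSE)

ens <- run_ensemble(matchup, CANDIDATES[[sel$best]], n_runs = 40,
                    seed = seeds[2])
print(ens)
jsonlite::write_json(
  list(n_runs = ens$n_runs, alpha = ens$alpha,
       smooth_summary = ens$smooth_summary, metrics = ens$metrics),
  file.path(OUT, "ensemble.json"), auto_unbox = TRUE, digits = 10)
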