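# Binomial additive mixed habitat model: dataset assembly at a 1:1
# presence:pseudoabsence ratio, GVIF multicollinearity screening,
# penalized-spline logistic fit with a per-individual random intercept,
# AIC/AUC model selection, and the repeated-fit ensemble over resampled
# null draws.

#' Assemble the 1:1 modeling dataset
#'
#' For each individual keeps the trip with the most records in the
#' matchup table (ties broken by longer date span, then lexicographically
#' smallest trip id) and pairs its presence records with the records of
#' one randomly selected retained null simulation of the same trip.
#' Individuals without any pseudoabsence records are dropped with a
#' warning.
#'
#' @param matchup Matchup table from [build_matchup_table()] with a
#'   `sim_id` column distinguishing null draws.
#' @param seed Integer seed for the per-trip null selection.
#' @return Data frame with a binary `presence` column (1 = presence) and
#'   `animal_id` coerced to factor.
#' @export
assemble_dataset <- function(matchup, seed = 1L) {
  ids <- unique(matchup$animal_id)
  if (length(ids) < 2) stop("need >= 2 individuals with complete trips")
  seeds <- split_seed(seed, length(ids))
  rows <- list()
  for (k in seq_along(ids)) {
    a <- ids[k]
    pres <- matchup[matchup$animal_id == a & matchup$source == "presence", ]
    if (nrow(pres) == 0) next
    per_trip <- split(pres, pres$trip_id)
    n_loc <- vapply(per_trip, nrow, 0L)
    span <- vapply(per_trip, function(x)
      as.numeric(max(x$date) - min(x$date)), 0)
    ord <- order(-n_loc, -span, names(per_trip))
    best <- names(per_trip)[ord[1]]
    abs_pool <- matchup[matchup$animal_id == a &
                          matchup$source == "pseudoabsence" &
                          matchup$trip_id == best, ]
    if (nrow(abs_pool) == 0) {
      warning("individual ", a, " has no retained null records; excluded")
      next
    }
    set.seed(seeds[k])
    sims <- unique(abs_pool$sim_id)
    pick <- sims[sample.int(length(sims), 1)]
    rows[[length(rows) + 1]] <- rbind(per_trip[[best]],
                                      abs_pool[abs_pool$sim_id == pick, ])
  }
  if (length(rows) < 2) stop("need >= 2 individuals with complete trips")
  out <- do.call(rbind, rows)
  out$presence <- as.integer(out$source == "presence")
  out$animal_id <- factor(out$animal_id)
  rownames(out) <- NULL
  out
}

#' Generalized variance inflation factors
#'
#' GVIF per covariate from the linear design, with the
#' `GVIF^(1/(2 df)) > 2` flag commonly used to screen multicollinearity.
#'
#' @param table Modeling table with a `presence` column.
#' @param covariates Character vector (>= 2) of covariate columns.
#' @return Data frame: covariate, df, gvif, gvif_adj
#'   (`GVIF^(1/(2 df))`), flagged.
#' @export
gvif_check <- function(table, covariates) {
  stopifnot(length(covariates) >= 2)
  f <- stats::as.formula(paste("presence ~", paste(covariates, collapse = "+")))
  fit <- stats::lm(f, data = table)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop("rank-deficient design; aliased: ",
         paste(rownames(al), collapse = ", "))
  v <- car::vif(fit)
  if (is.matrix(v)) {
    df <- v[, "Df"]; gvif <- v[, "GVIF"]
  } else {
    df <- rep(1, length(v)); gvif <- v
  }
  out <- data.frame(covariate = covariates, df = as.numeric(df),
                    gvif = as.numeric(gvif))
  out$gvif_adj <- out$gvif^(1 / (2 * out$df))
  out$flagged <- out$gvif_adj > 2
  out
}

#' ROC area under the curve
#'
#' Mann-Whitney normalization: the probability that a random positive
#' outscores a random negative, ties counted half.
#'
#' @param labels Binary vector (0/1 or logical).
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the binomial additive mixed habitat model
#'
#' Additive logistic regression with penalized cubic-spline smooths
#' (basis dimension `k`, default 4) for each covariate and a penalized
#' per-individual random intercept (`bs = "re"`), smoothing parameters by
#' REML. Reports per-smooth effective degrees of freedom, Wald chi-square
#' and p-value, AIC, in-sample AUC, adjusted deviance explained, the
#' random-intercept variance, and centred partial-response curves with
#' pointwise 95% intervals.
#'
#' @param table Assembled modeling table ([assemble_dataset()]).
#' @param covariates Character vector of covariate columns.
#' @param k Smooth basis dimension (>= 3).
#' @return Object of class `habitat_fit`: the `mgcv` fit plus extracted
#'   summaries (`smooth_table`, `aic`, `auc`, `deviance_explained`,
#'   `re_variance`, `partial` list of per-covariate response curves).
#' @export
fit_binomial_gamm <- function(table, covariates, k = 4) {
  stopifnot(k >= 3, all(covariates %in% names(table)))
  table$animal_id <- factor(table$animal_id)
  sm <- paste(sprintf("s(%s, k = %d, bs = 'cr')", covariates, k),
              collapse = " + ")
  f <- stats::as.formula(
    paste("presence ~", sm, "+ s(animal_id, bs = 're')"))
  fit <- mgcv::gam(f, data = table, family = stats::binomial(link = "logit"),
                   method = "REML")
  if (!fit$converged) stop("GAMM did not converge")
  sy <- mgcv::summary.gam(fit)
  st <- as.data.frame(sy$s.table)
  names(st) <- c("edf", "ref_df", "chisq", "p_value")
  st$term <- rownames(sy$s.table)
  cov_rows <- st[match(sprintf("s(%s)", covariates), st$term), ]
  cov_rows$covariate <- covariates
  vc <- tryCatch({
    v <- mgcv::gam.vcomp(fit)
    if (is.matrix(v)) v["s(animal_id)", "std.dev"]^2 else NA_real_
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  p_hat <- as.numeric(stats::fitted(fit))
  partial <- lapply(covariates, function(v) {
    xr <- range(table[[v]])
    nd <- table[rep(1, 100), c(covariates, "animal_id"), drop = FALSE]
    for (w in covariates) nd[[w]] <- stats::median(table[[w]])
    nd[[v]] <- seq(xr[1], xr[2], length.out = 100)
    nd$animal_id <- factor(levels(table$animal_id)[1],
                           levels = levels(table$animal_id))
    pr <- mgcv::predict.gam(fit, newdata = nd, type = "terms", se.fit = TRUE)
    cn <- sprintf("s(%s)", v)
    data.frame(x = nd[[v]], fit = pr$fit[, cn], se = pr$se.fit[, cn],
               lower = pr$fit[, cn] - 1.96 * pr$se.fit[, cn],
               upper = pr$fit[, cn] + 1.96 * pr$se.fit[, cn])
  })
  names(partial) <- covariates
  structure(list(
    gam = fit, covariates = covariates, k = k,
    smooth_table = cov_rows[c("covariate", "edf", "chisq", "p_value")],
    aic = stats::AIC(fit),
    auc = roc_auc(table$presence, p_hat),
    deviance_explained = as.numeric(sy$dev.expl),
    re_variance = vc,
    n = nrow(table), partial = partial), class = "habitat_fit")
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat(sprintf(
    "habitat_fit: n = %d, AIC = %.2f, AUC = %.3f, deviance explained = %.2f\n",
    x$n, x$aic, x$auc, x$deviance_explained))
  print(x$smooth_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Select among candidate covariate sets
#'
#' Fits each candidate and ranks by AIC (ascending). When the AIC-best
#' candidate is not also AUC-best the conflict is reported and the
#' AIC-best is chosen; exact ties keep declaration order.
#'
#' @param candidates Named list of covariate character vectors.
#' @param table Assembled modeling table.
#' @param k Smooth basis dimension.
#' @return List: `best` (candidate name), `ranking` (data.frame with AIC
#'   and AUC), `conflict` (logical), `fits` (per-candidate `habitat_fit`).
#' @export
select_model <- function(candidates, table, k = 4) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  fits <- lapply(candidates, fit_binomial_gamm, table = table, k = k)
  rk <- data.frame(candidate = names(candidates),
                   aic = vapply(fits, function(f) f$aic, 0),
                   auc = vapply(fits, function(f) f$auc, 0))
  rk <- rk[order(rk$aic, seq_len(nrow(rk))), ]
  best <- rk$candidate[1]
  auc_best <- rk$candidate[which.max(rk$auc)]
  conflict <- auc_best != best
  if (conflict)
    message("AIC-best (", best, ") differs from AUC-best (", auc_best,
            "); choosing AIC-best")
  list(best = best, ranking = rk, conflict = conflict, fits = fits)
}

#' Repeated-fit ensemble over resampled null draws
#'
#' Re-selects one retained null per trip (seeded), re-assembles the 1:1
#' dataset and refits `n_runs` times; tallies how often each covariate is
#' significant at `alpha` and aggregates mean (min-max) of edf,
#' chi-square, AIC, AUC and deviance explained.
#'
#' @param matchup Matchup table with the full retained-null pool.
#' @param covariates Covariate set to fit.
#' @param n_runs Number of runs (default 40).
#' @param alpha Significance level for the tally (default 0.001).
#' @param seed Integer master seed.
#' @param k Smooth basis dimension.
#' @return Object of class `habitat_ensemble`: `n_runs`, `alpha`,
#'   `n_significant` (per covariate), `smooth_summary` (per covariate
#'   mean/min/max of edf and chi-square), `metrics` (mean/min/max of AIC,
#'   AUC, deviance explained), `runs` (per-run metric table).
#' @export
run_ensemble <- function(matchup, covariates, n_runs = 40, alpha = 0.001,
                         seed = 1L, k = 4) {
  seeds <- split_seed(seed, n_runs)
  per_run <- vector("list", n_runs)
  failures <- 0
  for (r in seq_len(n_runs)) {
    res <- tryCatch({
      tab <- assemble_dataset(matchup, seed = seeds[r])
      fit <- fit_binomial_gamm(tab, covariates, k = k)
      list(smooth = fit$smooth_table, aic = fit$aic, auc = fit$auc,
           dev = fit$deviance_explained)
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1 else per_run[[r]] <- res
  }
  if (failures > 0.1 * n_runs)
    stop(failures, "/", n_runs, " ensemble runs failed")
  per_run <- Filter(Negate(is.null), per_run)
  n_ok <- length(per_run)
  sig <- sapply(per_run, function(r) r$smooth$p_value < alpha)
  edf <- sapply(per_run, function(r) r$smooth$edf)
  chi <- sapply(per_run, function(r) r$smooth$chisq)
  if (is.null(dim(sig))) { sig <- rbind(sig); edf <- rbind(edf); chi <- rbind(chi) }
  agg3 <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  smooth_summary <- data.frame(
    covariate = covariates,
    n_significant = as.integer(rowSums(sig)),
    edf_mean = rowMeans(edf), edf_min = apply(edf, 1, min),
    edf_max = apply(edf, 1, max),
    chisq_mean = rowMeans(chi), chisq_min = apply(chi, 1, min),
    chisq_max = apply(chi, 1, max))
  metr <- data.frame(
    aic = vapply(per_run, function(r) r$aic, 0),
    auc = vapply(per_run, function(r) r$auc, 0),
    deviance_explained = vapply(per_run, function(r) r$dev, 0))
  structure(list(
    n_runs = n_runs, n_ok = n_ok, alpha = alpha,
    n_significant = stats::setNames(smooth_summary$n_significant, covariates),
    smooth_summary = smooth_summary,
    metrics = list(aic = agg3(metr$aic), auc = agg3(metr$auc),
                   deviance_explained = agg3(metr$deviance_explained)),
    runs = metr), class = "habitat_ensemble")
}

#' @export
print.habitat_ensemble <- function(x, ...) {
  cat(sprintf("habitat_ensemble: %d/%d runs, alpha = %g\n",
              x$n_ok, x$n_runs, x$alpha))
  s <- x$smooth_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-14s edf %.1f (%.1f-%.1f)  chi2 %.1f (%.1f-%.1f)  n-sig %d/%d\n",
                s$covariate[i], s$edf_mean[i], s$edf_min[i], s$edf_max[i],
                s$chisq_mean[i], s$chisq_min[i], s$chisq_max[i],
                s$n_significant[i], x$n_ok))
  m <- x$metrics
  cat(sprintf("  AIC %.2f (%.2f-%.2f)  AUC %.3f (%.3f-%.3f)  dev.expl %.2f (%.2f-%.2f)\n",
              m$aic["mean"], m$aic["min"], m$aic["max"],
              m$auc["mean"], m$auc["min"], m$auc["max"],
              m$deviance_explained["mean"], m$deviance_explained["min"],
              m$deviance_explained["max"]))
  invisible(x)
}
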