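# fit a tiny habitat model on synthetic matchup data for surface tests
fit_small <- function(env, seed = 3) {
  set.seed(seed)
  g <- expand.grid(lon = env$lon[seq(2, length(env$lon), 2)],
                   lat = env$lat[seq(2, length(env$lat), 2)])
  g <- g[!is_land(env, g$lon, g$lat), ]
  g <- g[sample(nrow(g), 60), ]
  pos <- data.frame(animal_id = rep(c("a1", "a2", "a3"), each = 20),
                    trip_id = rep(c("a1_t01", "a2_t01", "a3_t01"), each = 20),
                    date = rep(env$time[3], 60), lon = g$lon, lat = g$lat)
  tab <- build_matchup_table(pos, pos, env, c(-120.5, 34))
  tab$presence <- rbinom(nrow(tab), 1, stats::plogis(tab$sst - 15))
  tab$presence[1:2] <- c(0, 1)
  fit_binomial_gamm(tab, c("sst", "bathymetry"))
}

test_that("a zeroed model predicts one half everywhere at sea", {
  env <- small_env(noise = FALSE)
  fit <- fit_small(env)
  fit$gam$coefficients[] <- 0
  ps <- predict_daily(fit, env, env$time[3], grid_step = 0.5)
  vals <- ps$values[!is.na(ps$values)]
  expect_true(all(abs(vals - 0.5) < 1e-12))
  # land cells are masked
  land_idx <- which(is_land(env, rep(ps$lon, length(ps$lat)),
                            rep(ps$lat, each = length(ps$lon))))
  expect_true(all(is.na(ps$values[land_idx])))
})

test_that("identical environmental days give identical surfaces", {
  env <- small_env(noise = FALSE)
  for (v in names(env$vars)) env$vars[[v]][, , 5] <- env$vars[[v]][, , 3]
  fit <- fit_small(env)
  s3 <- predict_daily(fit, env, env$time[3], grid_step = 0.5)
  s5 <- predict_daily(fit, env, env$time[5], grid_step = 0.5)
  expect_identical(s3$values, s5$values)
})

test_that("surface values reproduce population-level record predictions", {
  env <- small_env(noise = FALSE)
  fit <- fit_small(env)
  # a record sitting exactly on a surface cell centre
  lon0 <- env$lon[9]; lat0 <- env$lat[11]
  ps <- predict_daily(fit, env, env$time[3], grid_step = 0.25)
  cell <- ps$values[which(ps$lon == lon0), which(ps$lat == lat0)]
  cov <- crwhabitat:::raw_covariates(env, lon0, lat0, env$time[3])
  cov$chl <- log10(cov$chl); cov$eke <- log10(cov$eke)
  cov$bathymetry_sd <- sqrt(cov$bathymetry_sd)
  lev <- levels(fit$gam$model$animal_id)
  nd <- cbind(cov, animal_id = factor(lev[1], levels = lev))
  ref <- as.numeric(mgcv::predict.gam(fit$gam, nd, type = "response",
                                      exclude = "s(animal_id)",
                                      newdata.guaranteed = TRUE))
  expect_equal(cell, ref, tolerance = 1e-8)
})

test_that("rescaling maps the unmasked surface onto the unit interval", {
  env <- small_env(noise = FALSE)
  fit <- fit_small(env)
  ps <- predict_daily(fit, env, env$time[3], grid_step = 0.5, rescale = TRUE)
  vals <- ps$values[!is.na(ps$values)]
  expect_equal(range(vals), c(0, 1))
})

test_that("seasonal composites average cellwise with exact SEs", {
  mk <- function(vals) structure(list(
    lon = c(0, 1), lat = c(0, 1), date = as.Date("2006-11-01"),
    grid_step = 1, values = matrix(vals, 2, 2)),
    class = "prediction_surface")
  five <- replicate(5, mk(c(0.2, 0.4, 0.6, NA)), simplify = FALSE)
  comp <- seasonal_composite(five)
  expect_equal(comp$mean[1, 1], 0.2)
  expect_equal(comp$se[2, 1], 0)
  expect_true(is.na(comp$mean[2, 2]))
  expect_equal(comp$n_days[2, 2], 0)

  two <- list(mk(rep(0.2, 4)), mk(rep(0.6, 4)))
  comp2 <- seasonal_composite(two)
  expect_equal(comp2$mean[1, 1], 0.4)
  expect_equal(comp2$se[1, 1], stats::sd(c(0.2, 0.6)) / sqrt(2))

  # permutation invariance in day order
  set.seed(5)
  surfs <- replicate(4, mk(stats::runif(4)), simplify = FALSE)
  c1 <- seasonal_composite(surfs)
  c2 <- seasonal_composite(rev(surfs))
  expect_equal(c1$mean, c2$mean)
  expect_equal(c1$se, c2$se)

  bad <- list(mk(rep(0.1, 4)),
              structure(list(lon = c(0, 2), lat = c(0, 1),
                             values = matrix(0.1, 2, 2)),
                        class = "prediction_surface"))
  expect_error(seasonal_composite(bad), "identical grids")
})
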