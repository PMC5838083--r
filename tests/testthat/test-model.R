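test_that("dataset assembly keeps the best trip and balances classes", {
  set.seed(3)
  mt <- make_matchup(c("a1", "a2", "a3"), trips_per_id = 2)
  tab <- assemble_dataset(mt, seed = 5)
  # the second trip has more days and must be the one kept
  expect_true(all(grepl("_t02$", tab$trip_id)))
  expect_equal(sum(tab$presence == 1), sum(tab$presence == 0))
  # one sim per trip: pseudoabsence rows share a single sim_id per animal
  for (a in unique(tab$animal_id)) {
    sims <- unique(tab$sim_id[tab$animal_id == a & tab$presence == 0])
    expect_length(sims, 1)
  }
  expect_s3_class(tab$animal_id, "factor")
})

test_that("assembly tie-breaks use duration then trip id", {
  set.seed(4)
  mt <- make_matchup(c("a1", "a2"), trips_per_id = 1, n_days = 5)
  # give a1 a second trip with equally many locations but a wider span
  t2 <- mt[mt$trip_id == "a1_t01", ]
  t2$trip_id <- "a1_t00"
  t2$date <- as.Date("2006-11-01") + c(0, 3, 6, 9, 12, 15)
  tab <- assemble_dataset(rbind(mt, t2), seed = 1)
  expect_true(all(tab$trip_id == "a1_t00" | tab$animal_id != "a1"))
  expect_error(assemble_dataset(mt[0, ], seed = 1), ">= 2 individuals")
})

test_that("GVIF matches closed-form VIF behaviour", {
  set.seed(7)
  n <- 10000
  tab <- data.frame(presence = rbinom(n, 1, 0.5),
                    a = stats::rnorm(n), b = stats::rnorm(n),
                    c = stats::rnorm(n))
  g <- gvif_check(tab, c("a", "b", "c"))
  expect_true(all(g$gvif >= 1 & g$gvif < 1.1))
  expect_false(any(g$flagged))

  tab$d <- tab$a
  expect_error(gvif_check(tab, c("a", "b", "d")), "aliased")

  r <- 0.99
  tab$e <- r * tab$a + sqrt(1 - r^2) * stats::rnorm(n)
  g2 <- gvif_check(tab, c("a", "e"))
  expect_true(all(g2$flagged))
  expect_equal(g2$gvif[1], 1 / (1 - stats::cor(tab$a, tab$e)^2),
               tolerance = 0.05)
})

test_that("AUC equals the Mann-Whitney normalization with half ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC matches brute-force all-pairs counting", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    sc <- round(stats::rnorm(n), sample(0:2, 1))  # force some ties
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_identical(roc_auc(lab, sc), mean(cmp))
  }
})

test_that("permuting labels centres AUC on one half", {
  set.seed(17)
  sc <- stats::rnorm(200)
  lab <- rbinom(200, 1, 0.5)
  aucs <- replicate(50, roc_auc(sample(lab), sc))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the additive model is calibrated under the null", {
  set.seed(19)
  hits <- 0; reps <- 50
  for (r in 1:reps) {
    n <- 300
    tab <- data.frame(presence = rbinom(n, 1, 0.5),
                      x = stats::rnorm(n), z = stats::rnorm(n),
                      animal_id = factor(rep(1:10, each = n / 10)))
    fit <- fit_binomial_gamm(tab, c("x", "z"))
    hits <- hits + sum(fit$smooth_table$p_value < 0.001)
  }
  # 100 smooth tests at alpha .001: a handful of hits at most
  expect_lte(hits, 3)
})

test_that("a strong monotone effect is detected with a monotone response", {
  set.seed(23)
  n <- 400
  x <- stats::rnorm(n)
  tab <- data.frame(presence = rbinom(n, 1, stats::plogis(2 * x)), x = x,
                    animal_id = factor(rep(1:10, each = n / 10)))
  fit <- fit_binomial_gamm(tab, "x")
  expect_lt(fit$smooth_table$p_value, 1e-6)
  expect_gte(fit$auc, 0.8)
  p <- fit$partial$x
  central <- p$fit[p$x >= stats::quantile(x, .05) &
                     p$x <= stats::quantile(x, .95)]
  expect_true(all(diff(central) >= -1e-8))
  expect_gte(stats::cor(p$fit, 2 * p$x, method = "spearman"), 0.9)
})

test_that("a zero between-individual effect yields a tiny variance", {
  set.seed(29)
  vcs <- replicate(5, {
    n <- 400
    x <- stats::rnorm(n)
    tab <- data.frame(presence = rbinom(n, 1, stats::plogis(x)), x = x,
                      animal_id = factor(rep(1:10, each = n / 10)))
    fit_binomial_gamm(tab, "x")$re_variance
  })
  expect_lt(stats::median(vcs), 0.01)
})

test_that("model selection ranks by AIC and reports AUC conflicts", {
  set.seed(31)
  n <- 300
  x <- stats::rnorm(n); z <- stats::rnorm(n)
  tab <- data.frame(presence = rbinom(n, 1, stats::plogis(1.5 * x)),
                    x = x, z = z,
                    animal_id = factor(rep(1:10, each = n / 10)))
  sel <- select_model(list(active = "x", noise = "z", both = c("x", "z")),
                      tab)
  expect_true(sel$best %in% c("active", "both"))
  expect_equal(sel$ranking$candidate[1], sel$best)
  expect_true(all(diff(sel$ranking$aic) >= 0))
  # identical candidates: declaration order breaks the tie
  sel2 <- select_model(list(first = "x", second = "x"), tab)
  expect_equal(sel2$best, "first")
})

test_that("the ensemble aggregates run statistics coherently", {
  set.seed(37)
  mt <- make_matchup(c("a1", "a2", "a3", "a4"), trips_per_id = 1,
                     n_days = 8, n_sims = 3)
  ens <- run_ensemble(mt, c("sst", "bathymetry"), n_runs = 8, seed = 41)
  expect_equal(ens$n_ok, 8)
  s <- ens$smooth_summary
  expect_true(all(s$edf_min <= s$edf_mean & s$edf_mean <= s$edf_max))
  expect_true(all(s$n_significant <= ens$n_runs))
  for (m in ens$metrics)
    expect_true(m["min"] <= m["mean"] && m["mean"] <= m["max"])

  # a single sim per trip: no resampling variability across runs
  mt1 <- make_matchup(c("a1", "a2", "a3"), trips_per_id = 1, n_sims = 1)
  ens1 <- run_ensemble(mt1, c("sst", "bathymetry"), n_runs = 4, seed = 43)
  expect_equal(ens1$metrics$aic[["min"]], ens1$metrics$aic[["max"]])
  expect_true(all(ens1$smooth_summary$n_significant %in% c(0L, 4L)))
})
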