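make_fake_fit <- function(model, loglik, n_params = 5L, n_obs = 100L) {
  structure(list(model = model, loglik = loglik, n_params = n_params,
    n_obs = n_obs, conds = training_conditions(),
    fsp_args = list(tol = 1e-4, max_count = 128)),
    class = "sigburst_fit")
}

test_that("BIC follows k log(n) - 2 logL", {
  expect_equal(bic(-1000, 10, 5000), 10 * log(5000) + 2000)
  expect_equal(bic(-1000, 10, 5000), 2085.17, tolerance = 1e-5)
  expect_equal(bic(-42.5, 0, 17), 85)
  expect_error(bic(-10, 2, 0))
})

test_that("model ranking scores held-out data without refitting", {
  m <- toy_truth_model()
  d <- synthetic_design(conditions = "both", times = c(0, 3600),
    replicates = 1, cells_per_replicate = 150, seed = 55)
  test_tab <- generate_dataset(d, m)

  f1 <- make_fake_fit(m, -1000)
  r1 <- rank_models(list(f1), test_tab)
  expect_equal(nrow(r1), 1)
  expect_lte(r1$loglik_test, 0)
  expect_equal(r1$score, r1$loglik_train + r1$loglik_test)

  # a clearly worse parameterization of the same topology scores lower
  m2 <- m
  m2$name <- "worse"
  m2$genes$g$rates$delta <- m2$genes$g$rates$delta * 20
  f2 <- make_fake_fit(m2, -1000)
  r2 <- rank_models(list(f2, f1), test_tab)
  expect_equal(r2$model[1], "truth")

  # permuting input order leaves the ranking unchanged
  expect_equal(rank_models(list(f1, f2), test_tab), r2)

  # ties on the score break by lower BIC, then by name
  f3 <- make_fake_fit(m, -1000, n_params = 9L)
  r3 <- rank_models(list(f3, f1), test_tab)
  expect_equal(r3$bic, sort(r3$bic))
  m4 <- m; m4$name <- "aaa"
  f4 <- make_fake_fit(m4, -1000)
  r4 <- rank_models(list(f1, f4), test_tab)
  expect_equal(r4$model, c("aaa", "truth"))

  expect_error(rank_models(list(f1),
    dplyr::filter(test_tab, condition == "none")),
    class = "sigburst_error_config")
})

test_that("combined-drug prediction reduces to no-drug when substitutions are basal", {
  g <- toy_gene_3s("enhance")
  g$inhibitors <- inhibitor_map(b_mg132 = g$rates$b,
    k01_u0126 = g$rates$k[["01"]])
  m <- combinatorial_model("ident", toy_signal(), list(g = g))
  pred <- predict_combined(m, times = c(0, 3600, 14400),
    fsp_args = list(tol = 1e-6, max_count = 128))
  sol_none <- fsp_solve(g, "none", m$signal, c(0, 3600, 14400), tol = 1e-6,
    max_count = 128)
  marg <- sigburst:::marginal_matrix(sol_none)
  for (j in 1:3) {
    pj <- dplyr::filter(pred$distributions,
      time_s == c(0, 3600, 14400)[j])$probability
    expect_lt(tv_dist(pj, marg[, j] / sum(marg[, j])), 1e-9)
  }
  # distributions are renormalized at each time
  sums <- pred$distributions |>
    dplyr::summarise(s = sum(.data$probability), .by = c("gene", "time_s"))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)

  # prediction requires the substitution values
  g2 <- toy_gene_3s(); g2$inhibitors <- NULL
  expect_error(predict_combined(
    combinatorial_model("x", toy_signal(), list(g = g2))),
    class = "sigburst_error_config")
})

test_that("prediction is a pure function of the stored estimates", {
  m <- combinatorial_model("toy1", toy_signal(), list(g = toy_gene_3s()))
  fa <- list(tol = 1e-5, max_count = 128)
  dir <- withr::local_tempdir()
  p1 <- predict_combined(m, times = c(0, 3600), fsp_args = fa)
  p2 <- predict_combined(m, times = c(0, 3600), fsp_args = fa)
  write_prediction(p1, file.path(dir, "a"))
  write_prediction(p2, file.path(dir, "b"))
  expect_identical(readBin(file.path(dir, "a_prediction.json"), "raw", 1e6),
    readBin(file.path(dir, "b_prediction.json"), "raw", 1e6))
  expect_identical(p1$distributions, p2$distributions)
})

test_that("combined inhibition is predicted below the drug-free response", {
  cm1 <- cm_model("CM1")
  times <- design_times()
  pred <- predict_combined(cm1, times = times)
  none_mean <- purrr::imap_dfr(cm1$genes, function(g, nm) {
    sol <- fsp_solve(g, "none", cm1$signal, times, tol = 1e-4)
    dplyr::mutate(fsp_moments(sol), gene = nm)
  })
  both_mean <- pred$moments
  for (nm in names(cm1$genes)) {
    for (tt in times[-1]) {  # identical stationary init at t = 0
      expect_lt(
        both_mean$mean[both_mean$gene == nm & both_mean$time_s == tt],
        none_mean$mean[none_mean$gene == nm & none_mean$time_s == tt])
    }
  }
})

test_that("rate summaries reproduce the fitted-parameter ratios", {
  cm1 <- cm_model("CM1")
  s1 <- summarize_rates(cm1)
  val <- function(tab, g, r) tab$value[tab$gene == g & tab$ratio == r]
  expect_equal(val(s1, "tnfa", "k10/k01"), 4.67e-2 / 1.21e-4)
  expect_equal(val(s1, "tnfa", "k10/k01"), 385, tolerance = 5e-3)
  expect_equal(val(s1, "il1b", "b/b_mg132"), 3.4, tolerance = 2e-2)
  expect_equal(val(s1, "il1b", "k21/k12"), 213, tolerance = 5e-3)

  # identical numerator and denominator gives exactly 1
  g <- toy_gene_3s()
  g$inhibitors <- inhibitor_map(b_mg132 = g$rates$b,
    k01_u0126 = g$rates$k[["01"]])
  s2 <- summarize_rates(combinatorial_model("ident", toy_signal(),
    list(g = g)))
  expect_equal(val(s2, "g", "b/b_mg132"), 1)
  expect_equal(val(s2, "g", "k01/k01_u0126"), 1)

  # degradation rates agree between the two fitted models within 10%
  s3 <- summarize_rates(cm1, other = cm_model("CM2"))
  dd <- s3$value[s3$ratio == "delta_rel_diff" & s3$gene == "il1b"]
  expect_equal(dd, abs(5.67e-5 - 5.27e-5) / 5.67e-5)
  expect_lt(dd, 0.10)
})
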