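test_that("KL divergence follows the definition with a floored model law", {
  p <- c(0.5, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  # direct two-term sum: 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(kl_divergence(p, c(0.25, 0.75)),
    0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(p, c(0.25, 0.75)), 0.14384, tolerance = 1e-4)
  # flooring keeps the divergence finite at an impossible observation
  expect_equal(kl_divergence(c(1, 0), c(0, 1)), log(1 / 1e-12))
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)),
    class = "sigburst_error_config")
  set.seed(14)
  for (i in 1:10) {
    p <- as.numeric(rmultinom(1, 50, runif(6))) / 50
    q <- runif(6); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("the KL objective is the multinomial log-likelihood up to entropy", {
  tab <- toy_table()
  model <- toy_truth_model()
  conds <- c("none", "mg132")
  fa <- toy_fsp_args()
  ll <- dataset_loglik(tab, model, conds, fsp_args = fa)
  kl <- dataset_kl(tab, model, conds, fsp_args = fa)
  # the entropy constant depends on the data only
  ent <- 0
  for (cond in conds) {
    for (tt in unique(tab$time_s)) {
      p <- empirical_distribution(tab, "g", cond, tt, fa$max_count)
      nz <- p > 0
      ent <- ent - attr(p, "n_cells") * sum(p[nz] * log(p[nz]))
    }
  }
  expect_equal(-ll, kl + ent, tolerance = 1e-8)
})

test_that("the log-likelihood is weighted by cells and order-invariant", {
  tab <- dplyr::filter(toy_table(), .data$condition == "none")
  model <- toy_truth_model()
  fa <- toy_fsp_args()
  ll1 <- dataset_loglik(tab, model, "none", fsp_args = fa)
  expect_lt(ll1, 0)

  # doubling every cell record exactly doubles the log-likelihood
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(tab, cell_id = cell_id + 1e6))
  expect_equal(dataset_loglik(tab2, model, "none", fsp_args = fa), 2 * ll1,
    tolerance = 1e-10)

  # invariant to cell order and to replicate relabeling
  tab3 <- dplyr::arrange(tab, dplyr::desc(.data$cell_id), .data$time_s)
  expect_equal(dataset_loglik(tab3, model, "none", fsp_args = fa), ll1)
  tab4 <- dplyr::mutate(tab, replicate = rep_len(1:3, nrow(tab)))
  expect_equal(dataset_loglik(tab4, model, "none", fsp_args = fa), ll1)

  # a table whose empirical law equals the model marginal has ll = -n H(p)
  sol <- fsp_solve(model$genes$g, "none", model$signal, c(0), tol = 1e-6,
    max_count = fa$max_count)
  M <- sol$space$max_count
  q <- sigburst:::censored_model_marginal(sol)[, 1]
  counts <- rep(0:M, round(pmax(q, 0) * 1e6))
  tab5 <- tibble::tibble(replicate = 1, condition = "none", time_s = 0,
    cell_id = seq_along(counts), g_count = counts)
  fa5 <- list(tol = 1e-6, max_count = M)
  p5 <- empirical_distribution(tab5, "g", "none", 0, M)
  nz <- p5 > 0
  expect_equal(dataset_loglik(tab5, model, "none", fsp_args = fa5),
    length(counts) * sum(p5[nz] * log(pmax(q, 1e-12))[nz]), tolerance = 1e-9)
  expect_equal(dataset_kl(tab5, model, "none", fsp_args = fa5), 0,
    tolerance = length(counts) * 1e-4)
})

test_that("generating parameters outscore a badly perturbed copy", {
  tab <- toy_table()
  truth <- toy_truth_model()
  fa <- toy_fsp_args()
  worse <- truth
  worse$genes$g$rates$delta <- worse$genes$g$rates$delta * 10
  conds <- c("none", "mg132", "u0126")
  expect_gt(dataset_loglik(tab, truth, conds, fsp_args = fa),
    dataset_loglik(tab, worse, conds, fsp_args = fa))
})

test_that("the 1-D profile in delta peaks at the simulation truth", {
  tab <- toy_table()
  truth <- toy_truth_model()
  fa <- toy_fsp_args()
  delta0 <- truth$genes$g$rates$delta
  grid <- delta0 * 1.35^(-4:4)
  prof <- purrr::map_dbl(grid, function(dd) {
    m <- truth
    m$genes$g$rates$delta <- dd
    dataset_loglik(tab, m, c("none", "mg132", "u0126"), fsp_args = fa)
  })
  expect_lte(abs(which.max(prof) - 5), 1)  # within one grid step of truth
})

test_that("fit_model honors contracts: training set, bounds, determinism", {
  tab <- toy_table()
  template <- toy_truth_model()

  expect_error(fit_model(template, tab, conds = c("none", "both"),
    opt = opt_config(seed = 1)), class = "sigburst_error_training")
  expect_error(fit_model(template, dplyr::filter(tab, condition == "none"),
    conds = c("none", "mg132"), opt = opt_config(seed = 1)),
    class = "sigburst_error_config")
  expect_error(opt_config(seed = NULL), class = "sigburst_error_config")

  # cheap 2-parameter fit: everything else held at template values
  free <- c("g.delta", "g.alpha2")
  fixed <- setdiff(sigburst:::free_param_names(template,
    c("none", "mg132", "u0126")), free)
  template2 <- template
  template2$genes$g$rates$delta <- 8e-4     # start away from the truth
  template2$genes$g$rates$alpha[3] <- 0.1
  opt <- opt_config(n_starts = 2, maxit = 80, seed = 5, fixed = fixed,
    fsp_args = toy_fsp_args())
  fit1 <- fit_model(template2, tab, c("none", "mg132", "u0126"), opt = opt)
  fit2 <- fit_model(template2, tab, c("none", "mg132", "u0126"), opt = opt)
  expect_equal(fit1$loglik, fit2$loglik)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_equal(fit1$n_params, 2L)
  expect_equal(nrow(fit1$trace), 2)
  expect_true(is.finite(fit1$loglik))

  est <- tidy(fit1)
  expect_true(all(est$estimate >= 1e-7 & est$estimate <= 10))
  # optimization improved on the perturbed start
  ll_start <- dataset_loglik(tab, template2, c("none", "mg132", "u0126"),
    fsp_args = toy_fsp_args())
  expect_gte(fit1$loglik, ll_start)
  # and lands near the generating values for the two free parameters
  expect_equal(est$estimate[est$term == "g.delta"], 2e-4, tolerance = 0.3)
  expect_equal(est$estimate[est$term == "g.alpha2"], 0.04, tolerance = 0.3)

  gl <- glance(fit1)
  expect_equal(gl$BIC, 2 * log(gl$n_obs) - 2 * gl$logLik)
  expect_equal(gl$n_obs, 600L * 3L * 5L)

  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit1, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$loglik, fit1$loglik)
  expect_equal(js$parameters$g.delta,
    est$estimate[est$term == "g.delta"])
})
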