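test_that("generator columns balance, with transcription leak at the boundary", {
  g <- toy_gene_3s()
  sp <- toy_signal()

  # no transcription, max_count 0: a pure gene-switching chain, columns sum to 0
  g0 <- g
  g0$rates$alpha <- c(0, 0, 0)
  gen0 <- build_generator(g0, "none", state_space(3, 1), sp)
  A0 <- generator_matrix(gen0, 500)
  expect_lt(max(abs(Matrix::colSums(A0))), 1e-15)

  # generic model: off-diagonals >= 0, column deficits equal the leak rates
  space <- state_space(3, 20)
  gen <- build_generator(g, "none", space, sp)
  A <- as.matrix(generator_matrix(gen, 1234))
  offdiag <- A - diag(diag(A))
  expect_true(all(offdiag >= 0))
  expect_equal(-Matrix::colSums(A), gen$leak, tolerance = 1e-12,
    ignore_attr = TRUE)
  expect_true(all(gen$leak[space_index(space, 0:2, 20)] == g$rates$alpha))

  expect_error(
    build_generator(gene_model(g$topology,
      gene_rates(g$topology, k = g$rates$k, b = g$rates$b,
        alpha = c(0, 0, Inf), delta = 1e-4)), "none", space, sp),
    class = "sigburst_error_config")
})

test_that("frozen generator matches the dense Kolmogorov oracle", {
  # small 3-state model, point-mass init, signal frozen at a few levels
  g <- toy_gene_3s()
  sp <- toy_signal()
  M <- 30
  space <- state_space(3, M)
  init <- numeric(space$dim)
  init[space_index(space, 0, 0)] <- 1
  tab <- list(times = 0, values = 0.08)  # constant signal
  times <- c(0, 2000, 6000)

  sol <- fsp_solve(g, "none", sp, times, init = init, tol = 1,
    max_count = M, max_count_ceiling = M, signal_table = tab)
  ora <- oracle_solve_piecewise(g, "none", tab, times, M, init)
  for (j in seq_along(times)) {
    expect_lt(tv_dist(sol$prob[, j], ora$prob[, j]), 1e-8)
  }
  expect_equal(sol$sink_mass, ora$sink, tolerance = 1e-6)
})

test_that("FSP matches a piecewise-frozen signal oracle to TV 1e-6", {
  sp <- toy_signal()
  tab <- list(times = c(0, 1000, 3000, 8000),
              values = nfkb_signal(c(500, 2000, 5000, 10000), sp))
  times <- c(0, 1800, 3600, 7200, 14400)
  M <- 60
  for (mode in c("enhance", "suppress")) {
    g <- toy_gene_3s(mode)
    space <- state_space(3, M)
    init <- numeric(space$dim)
    init[space_index(space, 0, 2)] <- 1
    sol <- fsp_solve(g, "mg132", sp, times, init = init, tol = 1,
      max_count = M, max_count_ceiling = M, signal_table = tab)
    ora <- oracle_solve_piecewise(g, "mg132", tab, times, M, init)
    for (j in seq_along(times)) {
      expect_lt(tv_dist(oracle_marginal(sol$prob[, j], 3),
                        oracle_marginal(ora$prob[, j], 3)), 1e-6)
    }
  }
})

test_that("constitutive gene follows the closed-form immigration-death law", {
  g <- constitutive_gene(alpha = 1e-2, delta = 1e-4)  # alpha/delta = 100
  sp <- toy_signal()

  # stationary law is Poisson(100)
  p <- stationary_distribution(g, "none", sp)
  M <- attr(p, "space")$max_count
  expect_lt(tv_dist(p, dpois(0:M, 100)), 1e-8)

  # transient from empty cell: Poisson(100 (1 - e^{-delta t})), exactly
  times <- c(0, 3600, 14400, 43200)
  init <- numeric(257)
  init[1] <- 1
  sol <- fsp_solve(g, "none", sp, times, init = init, tol = 1e-8,
    max_count = 256)
  for (j in seq_along(times)) {
    lam <- 100 * (1 - exp(-1e-4 * times[j]))
    expect_lt(tv_dist(sol$prob[, j], dpois(0:sol$space$max_count, lam)), 1e-7)
  }
  mom <- fsp_moments(sol)
  expect_equal(mom$mean, 100 * (1 - exp(-1e-4 * times)), tolerance = 1e-6)
})

test_that("signal-free stationary law matches the analytic birth-death chain", {
  cm1 <- cm_model("CM1")
  tnfa <- cm1$genes$tnfa
  p <- stationary_distribution(tnfa, "none", cm1$signal)
  S <- 3
  occ <- rowSums(matrix(p, nrow = S))

  # analytic chain ratios from the rate constants
  r <- tnfa$rates$k
  pi_raw <- c(1, r[["01"]] / r[["10"]], r[["01"]] / r[["10"]] * r[["12"]] / r[["21"]])
  pi_an <- pi_raw / sum(pi_raw)
  expect_equal(occ, pi_an, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(occ, c(0.9921, 0.0026, 0.0053), tolerance = 2e-2,
    ignore_attr = TRUE)

  # first-moment identity at stationarity: mean = sum(alpha_i pi_i) / delta
  xs <- 0:attr(p, "space")$max_count
  mean_stat <- sum(xs * colSums(matrix(p, nrow = S)))
  mean_an <- sum(tnfa$rates$alpha * pi_an) / tnfa$rates$delta
  expect_equal(mean_stat, mean_an, tolerance = 1e-4)
  expect_equal(mean_stat, 19.6, tolerance = 5e-3)

  expect_error(
    stationary_distribution(
      gene_model(gene_topology(1), gene_rates(gene_topology(1), alpha = 0,
        delta = 1e-4)), "none", cm1$signal),
    class = "sigburst_error_config")
})

test_that("zero transcription keeps the mRNA marginal at zero", {
  g <- toy_gene_3s()
  g$rates$alpha <- c(0, 0, 0)
  space <- state_space(3, 5)
  init <- numeric(space$dim)
  init[space_index(space, 0, 0)] <- 1
  sol <- fsp_solve(g, "none", toy_signal(), design_times(), init = init,
    tol = 1e-9, max_count = 5)
  marg <- marginal_mrna(sol) |>
    dplyr::filter(.data$count > 0)
  expect_lt(max(marg$probability), 1e-9)
  expect_lt(max(sol$sink_mass), 1e-12)
})

test_that("marginals, occupancy and moments are consistent summaries", {
  g <- toy_gene_3s()
  sp <- toy_signal()
  space <- state_space(3, 40)
  init <- numeric(space$dim)
  init[space_index(space, 1, 5)] <- 1  # point mass at (G1, 5)
  sol <- fsp_solve(g, "none", sp, c(0, 1800), init = init, tol = 1,
    max_count = 40, max_count_ceiling = 40)

  m0 <- dplyr::filter(marginal_mrna(sol), time_s == 0)
  expect_equal(m0$probability[m0$count == 5], 1)
  occ0 <- dplyr::filter(state_occupancy(sol), time_s == 0)
  expect_equal(occ0$probability[occ0$state == "G1"], 1)

  # marginal and occupancy both sum to 1 - sink at every time
  for (j in seq_along(sol$times)) {
    tt <- sol$times[j]
    expect_equal(
      sum(dplyr::filter(marginal_mrna(sol), time_s == tt)$probability),
      1 - sol$sink_mass[j], tolerance = 1e-9)
    expect_equal(
      sum(dplyr::filter(state_occupancy(sol), time_s == tt)$probability),
      1 - sol$sink_mass[j], tolerance = 1e-9)
  }

  # with alpha = (0, 0, 1) the mean transcription rate is P(G2)
  g2 <- g
  g2$rates$alpha <- c(0, 0, 1)
  sol2 <- fsp_solve(g2, "none", sp, c(0, 900, 1800), tol = 1e-6,
    max_count = 400)
  mtr <- mean_transcription_rate(sol2)
  occ <- state_occupancy(sol2) |> dplyr::filter(.data$state == "G2")
  expect_equal(mtr$rate, occ$probability, tolerance = 1e-12)

  # occupancy at t = 0 under the default init equals the stationary marginal
  p <- stationary_distribution(g, "none", sp)
  sol3 <- fsp_solve(g, "none", sp, c(0, 600), tol = 1e-6)
  occ3 <- dplyr::filter(state_occupancy(sol3), time_s == 0)
  expect_equal(occ3$probability, rowSums(matrix(p, nrow = 3)),
    tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("probability is conserved and the sink certifies truncation", {
  g <- toy_gene_3s()
  sol <- fsp_solve(g, "none", toy_signal(), design_times(), tol = 1e-4)
  expect_true(all(sol$prob >= -1e-12))
  total <- colSums(sol$prob) + sol$sink_mass
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_true(all(diff(sol$sink_mass) >= -1e-12))
  expect_lte(sol$diagnostics$final_sink, 1e-4)

  # a deliberately tight initial truncation triggers adaptive expansion
  sol2 <- fsp_solve(g, "none", toy_signal(), design_times(), tol = 1e-6,
    max_count = 8)
  expect_gte(sol2$diagnostics$expansions, 1)
  expect_lte(sol2$diagnostics$final_sink, 1e-6)

  # and a hard ceiling turns overflow into a truncation-failure error
  expect_error(
    fsp_solve(g, "none", toy_signal(), design_times(), tol = 1e-12,
      max_count = 4, max_count_ceiling = 8),
    class = "sigburst_error_truncation")

  # init must be a distribution
  expect_error(
    fsp_solve(g, "none", toy_signal(), c(0, 10), init = rep(0.5, 12),
      max_count = 3), class = "sigburst_error_config")
})

test_that("FSP solutions export as TSV + JSON diagnostics", {
  sol <- fsp_solve(toy_gene_3s(), "none", toy_signal(), c(0, 1800),
    tol = 1e-4)
  prefix <- file.path(withr::local_tempdir(), "sol")
  paths <- export_fsp_solution(sol, prefix)
  expect_true(all(file.exists(paths)))
  marg <- utils::read.delim(paths[1])
  expect_named(marg, c("time_s", "state_or_count", "probability"))
  diag <- jsonlite::read_json(paths[3])
  expect_equal(diag$max_count, sol$space$max_count)
})
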