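test_that("NF-kB signal has the right shape and analytic maximizer", {
  sp <- toy_signal()  # CM1 signal rates
  expect_identical(nfkb_signal(0, sp), 0)
  expect_lt(nfkb_signal(1e7, sp), 1e-6)
  expect_error(nfkb_signal(-1, sp), class = "sigburst_error_domain")

  # analytic peak against a dense grid search (independent oracle)
  grid <- seq(0, 20000, by = 0.5)
  t_grid <- grid[which.max(exp(-sp$r1 * grid) * (1 - exp(-sp$r2 * grid)))]
  expect_equal(signal_peak_time(sp), t_grid, tolerance = 1 / t_grid)
  expect_equal(signal_peak_time(sp), 955.9, tolerance = 1e-4)
  expect_equal(nfkb_signal(signal_peak_time(sp), sp), 0.1069, tolerance = 1e-3)

  # non-negativity, boundedness, maximizer formula across random rates
  set.seed(42)
  for (i in 1:20) {
    spi <- signal_params(r1 = 10^runif(1, -5, -2), r2 = 10^runif(1, -5, -2))
    s <- nfkb_signal(seq(0, 1e5, length.out = 2000), spi)
    expect_true(all(s >= 0 & s < 1))
    tstar <- signal_peak_time(spi)
    eps <- 1e-3 * tstar
    expect_gte(nfkb_signal(tstar, spi),
      max(nfkb_signal(c(tstar - eps, tstar + eps), spi)))
  }
})

test_that("effective rates honor condition substitutions and the signal", {
  cm1 <- cm_model("CM1")
  tnfa <- cm1$genes$tnfa
  sp <- cm1$signal

  # at t = 0 the signal vanishes: every edge at its basal (substituted) rate
  r0 <- effective_rates(tnfa, "none", sp, 0)
  expect_equal(r0$k01, 1.21e-4)
  expect_equal(r0$k10, 4.67e-2)

  # MG132 swaps the signal coefficient: k01(t) = k01 + b_mg * s(t)
  t1 <- 955.9
  s1 <- exp(-sp$r1 * t1) * (1 - exp(-sp$r2 * t1))
  rmg <- effective_rates(tnfa, "mg132", sp, t1)
  expect_equal(rmg$k01, 1.21e-4 + 7.80e-3 * s1, tolerance = 1e-12)

  # drug-free rate at the signal peak, against direct substitution
  rn <- effective_rates(tnfa, "none", sp, t1)
  expect_equal(rn$k01, 1.21e-4 + 2.27e-2 * s1, tolerance = 1e-12)
  expect_equal(rn$k01, 2.548e-3, tolerance = 1e-3)

  # U0126 replaces the basal activation rate in all phases
  ru <- effective_rates(tnfa, "u0126", sp, c(0, t1))
  expect_equal(ru$k01[1], 1.00e-4)
  expect_equal(ru$k01[2], 1.00e-4 + 2.27e-2 * s1, tolerance = 1e-12)

  # combined condition == both substitutions, order-independent
  rboth <- effective_rates(tnfa, "both", sp, t1)
  expect_equal(rboth$k01, 1.00e-4 + 7.80e-3 * s1, tolerance = 1e-12)

  # MG132 never increases the signal-edge rate when b_mg <= b
  for (tt in c(0, 300, 955.9, 3600, 14400)) {
    expect_lte(effective_rates(tnfa, "mg132", sp, tt)$k01,
      effective_rates(tnfa, "none", sp, tt)$k01)
  }

  # suppress mode divides the deactivation rate
  il1b2 <- cm_model("CM2")$genes$il1b
  sp2 <- cm_model("CM2")$signal
  s2 <- nfkb_signal(t1, sp2)
  r2 <- effective_rates(il1b2, "none", sp2, t1)
  expect_equal(r2$k10, 7.66e-2 / (1 + 6.60 * s2), tolerance = 1e-12)
  r2lin <- effective_rates(il1b2, "none", sp2, t1, suppress_form = "linear")
  expect_equal(r2lin$k10, 7.66e-2 * max(0, 1 - 6.60 * s2), tolerance = 1e-12)

  # a condition needing substitutions fails without an inhibitor map
  g <- toy_gene_3s(); g$inhibitors <- NULL
  expect_error(effective_rates(g, "mg132", sp, 0),
    class = "sigburst_error_config")
})

test_that("the six candidate mechanisms enumerate correctly", {
  tops <- enumerate_single_gene_topologies()
  expect_length(tops, 6)
  expect_equal(sum(purrr::map_int(tops, "n_states") == 2), 2)
  expect_equal(sum(purrr::map_int(tops, "n_states") == 3), 4)
  for (top in tops) {
    # exactly one signal edge, on the adjacent-state chain
    expect_true(top$signal_edge %in% top$edges)
    expect_true(top$signal_mode %in% c("enhance", "suppress"))
    d <- abs(as.integer(substr(top$edges, 1, 1)) -
             as.integer(substr(top$edges, 2, 2)))
    expect_true(all(d == 1))
  }
  # the enhance-G1->G2 3-state variant is the CM1 IL-1b mechanism
  cm1_il1b <- cm_model("CM1")$genes$il1b$topology
  expect_true(cm1_il1b$name %in% names(tops))
  expect_identical(tops[[cm1_il1b$name]]$signal_edge, "12")
  expect_identical(tops[[cm1_il1b$name]]$signal_mode, "enhance")
  # a signal edge must run in the right direction for its mode
  expect_error(gene_topology(3, "10", "enhance"),
    class = "sigburst_error_config")
})

test_that("combinatorial model enumeration is a cartesian product with a shared signal", {
  tops <- enumerate_single_gene_topologies()
  three <- tops[c("3s_act01", "3s_act12", "3s_sup10")]
  sp <- toy_signal()
  m9 <- enumerate_combinatorial_models(list(il1b = three, tnfa = three), sp)
  expect_length(m9, 9)
  m36 <- enumerate_combinatorial_models(list(il1b = tops, tnfa = tops), sp)
  expect_length(m36, 36)
  expect_false(anyDuplicated(names(m36)) > 0)

  m1 <- enumerate_combinatorial_models(
    list(il1b = tops[1], tnfa = tops[2]), sp)
  expect_length(m1, 1)
  expect_identical(m1[[1]]$signal, sp)
  expect_error(enumerate_combinatorial_models(list(il1b = list(), tnfa = tops), sp),
    class = "sigburst_error_config")
})

test_that("model configs round-trip through YAML and JSON", {
  m <- toy_model()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_equal(get_model_params(m2, conditions()),
      get_model_params(m, conditions()))
    expect_identical(m2$genes$g1$topology$signal_edge, "01")
    expect_identical(m2$genes$g2$topology$signal_mode, "suppress")
  }
})
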