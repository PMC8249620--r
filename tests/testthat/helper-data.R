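# Lazily built, cached synthetic datasets shared across test files.

.sigburst_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sigburst_test_cache[[key]])) {
    .sigburst_test_cache[[key]] <- force(expr)
  }
  .sigburst_test_cache[[key]]
}

# single-gene 3-state training table at moderate depth
toy_table <- function() cached("toy_table", {
  truth <- combinatorial_model("truth", toy_signal(),
    list(g = toy_gene_3s("enhance")))
  d <- synthetic_design(conditions = c("none", "mg132", "u0126"),
    replicates = 1, cells_per_replicate = 600, seed = 101)
  generate_dataset(d, truth)
})

toy_truth_model <- function() {
  combinatorial_model("truth", toy_signal(), list(g = toy_gene_3s("enhance")))
}

toy_fsp_args <- function() list(tol = 1e-4, max_count = 128)

# full-scale CM1 TNF-alpha: FSP solution and 10,000 SSA cells at the design
# times (shared between the simulator/solver agreement tests)
cm1_tnfa_bench <- function() cached("cm1_tnfa_bench", {
  cm1 <- cm_model("CM1")
  times <- design_times()
  sol <- fsp_solve(cm1$genes$tnfa, "none", cm1$signal, times, tol = 1e-4)
  tr <- ssa_trajectory(cm1$genes$tnfa, "none", cm1$signal, times,
    seed = 20240717, n_cells = 10000)
  q <- sigburst:::marginal_matrix(sol)
  list(times = times, q = q,
    emp = purrr::map(times, function(tt) {
      x <- tr$count[tr$time_s == tt]
      tabulate(pmin(x, nrow(q) - 1L) + 1L, nbins = nrow(q)) / length(x)
    }),
    n_cells = 10000)
})
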