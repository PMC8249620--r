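ssa_model_spec <- function(gene, condition, sp,
                           suppress_form = "saturating") {
  rates <- condition_rates(gene, condition)
  top <- gene$topology
  efrom <- integer(0); eto <- integer(0); erate <- numeric(0)
  for (e in top$edges) {
    if (isTRUE(e == top$signal_edge)) next
    efrom <- c(efrom, as.integer(substr(e, 1, 1)))
    eto <- c(eto, as.integer(substr(e, 2, 2)))
    erate <- c(erate, unname(rates$k[[e]]))
  }
  se <- top$signal_edge
  none <- top$signal_mode == "none"
  list(
    n_states = top$n_states, efrom = efrom, eto = eto, erate = erate,
    sig_from = if (none) -1L else as.integer(substr(se, 1, 1)),
    sig_to = if (none) -1L else as.integer(substr(se, 2, 2)),
    sig_mode = sig_mode_code(top$signal_mode, suppress_form),
    sig_k = if (none) 0 else unname(rates$k[[se]]), sig_b = rates$b,
    r1 = sp$r1, r2 = sp$r2, alpha = rates$alpha, delta = rates$delta
  )
}

# batch of independent cells; uses the current R RNG state
ssa_cells <- function(gene, condition, sp, t_obs, n_cells, init = NULL,
                      thin_dt = 60, suppress_form = "saturating") {
  spec <- ssa_model_spec(gene, condition, sp, suppress_form)
  if (is.null(init)) {
    init <- stationary_distribution(gene, condition, sp,
      suppress_form = suppress_form)
  }
  ns <- attr(init, "space")$n_states %||% gene$topology$n_states
  ssa_cells_cpp(n_cells, spec, as.numeric(t_obs), as.numeric(init), ns,
    thin_dt)
}

#' Exact stochastic trajectory of a single cell
#'
#' Samples one trajectory of the time-inhomogeneous gene model by the direct
#' method with thinning against a per-interval upper bound on the
#' signal-edge rate (the bound is recomputed every `thin_dt` seconds). The
#' initial state is drawn from the same signal-free stationary distribution
#' that initializes [fsp_solve()].
#'
#' @inheritParams fsp_solve
#' @param t_grid Sorted observation times in seconds.
#' @param seed Integer seed (mandatory: every stochastic operation is
#'   explicitly seeded).
#' @param n_cells Number of independent cells to simulate.
#' @param thin_dt Interval (seconds) over which the thinning bound is frozen.
#' @return Tibble with columns `cell_id`, `time_s`, `state` (gene state
#'   label) and `count` (mRNA copies).
#' @export
ssa_trajectory <- function(gene, condition, sp, t_grid, seed, n_cells = 1,
                           init = NULL, thin_dt = 60,
                           suppress_form = c("saturating", "linear")) {
  suppress_form <- match.arg(suppress_form)
  stopifnot(!is.unsorted(t_grid), all(t_grid >= 0))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  res <- ssa_cells(gene, condition, sp, t_grid, n_cells, init = init,
    thin_dt = thin_dt, suppress_form = suppress_form)
  tidyr::expand_grid(cell_id = seq_len(n_cells), time_s = as.numeric(t_grid)) |>
    dplyr::mutate(state = paste0("G", as.vector(t(res$state))),
                  count = as.integer(as.vector(t(res$count))))
}

set_local_seed <- function(seed) {
  if (is.null(seed)) {
    rlang::abort("a seed is required for stochastic operations",
      class = "sigburst_error_config")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed)
  for (k in idx) s <- (s * 7919 + 104729 * as.numeric(k)) %% 2147483587
  as.integer(s) + 1L
}

#' Synthetic smFISH study design
#'
#' Replicates the measurement design: inhibitor conditions x five time
#' points after LPS (0, 30, 60, 120, 240 min) x independent biological
#' replicates, with a fixed number of cells measured per replicate and time.
#'
#' @param conditions Subset of [conditions()].
#' @param times Observation times in seconds, sorted, starting at 0.
#' @param replicates Number of biological replicates (i.i.d.; fitting pools
#'   them).
#' @param cells_per_replicate Cells per (condition, replicate, time).
#' @param seed Integer seed; per-replicate sub-seeds are derived
#'   deterministically from it.
#' @return A `sigburst_design` object.
#' @export
synthetic_design <- function(conditions = sigburst::conditions(),
                             times = c(0, 1800, 3600, 7200, 14400),
                             replicates = 4, cells_per_replicate = 500,
                             seed = NULL) {
  assert_condition(conditions)
  stopifnot(!is.unsorted(times, strictly = TRUE), times[1] == 0,
    replicates >= 1, cells_per_replicate >= 1)
  if (is.null(seed)) {
    rlang::abort("the design requires an explicit seed",
      class = "sigburst_error_config")
  }
  structure(list(conditions = conditions, times = as.numeric(times),
    replicates = as.integer(replicates),
    cells_per_replicate = as.integer(cells_per_replicate),
    seed = as.integer(seed)), class = "sigburst_design")
}

#' Generate a synthetic single-cell count table
#'
#' Simulates the full study design by exact stochastic simulation: for every
#' (condition, replicate, time), `cells_per_replicate` independent cells,
#' with the genes simulated independently given the shared deterministic
#' NF-kB signal (conditional independence). Counting is treated as exact
#' (no detection-efficiency parameter). Bit-for-bit reproducible for a fixed
#' design seed.
#'
#' @param design A [synthetic_design()].
#' @param model A [combinatorial_model()].
#' @param thin_dt,suppress_form Passed to the simulator.
#' @return Tibble with columns `replicate`, `condition`, `time_s`,
#'   `cell_id`, and one `<gene>_count` column per model gene.
#' @export
generate_dataset <- function(design, model, thin_dt = 60,
                             suppress_form = c("saturating", "linear")) {
  stopifnot(inherits(design, "sigburst_design"),
    inherits(model, "sigburst_model"))
  suppress_form <- match.arg(suppress_form)
  genes <- names(model$genes)
  # stationary initial laws once per (gene, condition)
  inits <- purrr::map(rlang::set_names(design$conditions), function(cond) {
    purrr::map(model$genes, stationary_distribution, condition = cond,
      sp = model$signal, suppress_form = suppress_form)
  })
  rows <- purrr::map_dfr(seq_along(design$conditions), function(ci) {
    cond <- design$conditions[ci]
    purrr::map_dfr(seq_len(design$replicates), function(rep_id) {
      old <- set_local_seed(derive_seed(design$seed, ci, rep_id))
      on.exit(restore_seed(old))
      purrr::map_dfr(design$times, function(tt) {
        counts <- purrr::map(genes, function(g) {
          res <- ssa_cells(model$genes[[g]], cond, model$signal, tt,
            design$cells_per_replicate, init = inits[[cond]][[g]],
            thin_dt = thin_dt, suppress_form = suppress_form)
          as.integer(res$count[, 1])
        })
        names(counts) <- paste0(genes, "_count")
        dplyr::bind_cols(
          tibble::tibble(replicate = rep_id, condition = cond, time_s = tt,
            cell_id = seq_len(design$cells_per_replicate)),
          tibble::as_tibble(counts))
      })
    })
  })
  rows
}

#' Write / read a count table as CSV
#'
#' Header `replicate,condition,time_s,cell_id,<gene>_count,...`; conditions
#' spelled `none|mg132|u0126|both`; UTF-8, LF line endings.
#'
#' @param table Count table tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_count_table <- function(table, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(as.data.frame(table), con, row.names = FALSE,
    quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Empirical mRNA copy-number distribution of a sample
#'
#' Normalized histogram of one gene's counts in one (condition, time) cell
#' sample, pooled over replicates. Counts above `max_count` are censored
#' into the top bin.
#'
#' @param table Count table (see [generate_dataset()]).
#' @param gene Gene name (matching a `<gene>_count` column).
#' @param condition,time Sample selectors (`time` in seconds).
#' @param max_count Top bin; support is `0..max_count`.
#' @return Numeric probability vector of length `max_count + 1` (sums to 1)
#'   with attribute `n_cells`, the number of cells used.
#' @export
empirical_distribution <- function(table, gene, condition, time, max_count) {
  col <- paste0(gene, "_count")
  stopifnot(col %in% names(table))
  x <- table[[col]][table$condition == condition & table$time_s == time]
  if (length(x) == 0) {
    rlang::abort(sprintf("no cells for gene '%s', condition '%s', time %g s",
      gene, condition, time), class = "sigburst_error_empty")
  }
  x <- pmin(x, max_count)
  p <- tabulate(x + 1L, nbins = max_count + 1L) / length(x)
  attr(p, "n_cells") <- length(x)
  p
}
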