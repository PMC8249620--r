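#' Truncated state space for the finite state projection
#'
#' The chain state is (gene state, mRNA copy number) with copy numbers
#' retained up to `max_count` inclusive; probability transcribed past the
#' boundary flows into an absorbing sink whose mass certifies the
#' truncation error.
#'
#' @param n_states Number of gene states.
#' @param max_count Largest retained mRNA copy number (>= 1).
#' @return A `sigburst_space` object.
#' @export
state_space <- function(n_states, max_count) {
  stopifnot(n_states >= 1, max_count >= 1)
  structure(list(n_states = as.integer(n_states),
                 max_count = as.integer(max_count),
                 dim = as.integer(n_states) * (as.integer(max_count) + 1L)),
            class = "sigburst_space")
}

# flat index of (gene state g in 0..S-1, count x in 0..M), 1-based
space_index <- function(space, g, x) x * space$n_states + g + 1L

sig_mode_code <- function(mode, suppress_form) {
  switch(mode %||% "none",
    enhance = 1L,
    suppress = if (suppress_form == "saturating") 2L else 3L,
    0L
  )
}

#' Build the time-varying CME generator on a truncated space
#'
#' Encodes gene-state switching at the per-edge rates, transcription at
#' `alpha[state]` (x -> x+1) and degradation at `delta * x` (x -> x-1) as a
#' sparse transition-rate matrix split as `A(t) = A_base + k_sig(t) * E`,
#' where `E` is the unit-rate generator of the single signal-modulated edge
#' and `k_sig(t)` its instantaneous rate. Columns at the `max_count`
#' boundary leak transcription flux to the truncation sink, so column sums
#' are <= 0.
#'
#' @inheritParams condition_rates
#' @param space A [state_space()].
#' @param sp A [signal_params()].
#' @param suppress_form Functional form of a suppressed edge, see
#'   [effective_rates()].
#' @param signal_table Optional list `list(times =, values =)` replacing the
#'   smooth signal by a piecewise-constant one (value `values[j]` on
#'   `[times[j], times[j+1])`).
#' @param reflect_top If `TRUE`, the boundary is reflecting (no transcription
#'   out of `max_count`, no sink leak); used for stationary solves.
#' @return A `sigburst_generator` object.
#' @export
build_generator <- function(gene, condition, space, sp,
                            suppress_form = c("saturating", "linear"),
                            signal_table = NULL, reflect_top = FALSE) {
  suppress_form <- match.arg(suppress_form)
  stopifnot(inherits(space, "sigburst_space"))
  rates <- condition_rates(gene, condition)
  top <- gene$topology
  stopifnot(top$n_states == space$n_states)
  if (any(!is.finite(unlist(rates[c("k", "b", "alpha", "delta")])))) {
    rlang::abort("non-finite rate", class = "sigburst_error_config")
  }
  S <- space$n_states
  M <- space$max_count
  n <- space$dim
  xs <- 0:M

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  add <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v)
  }
  # switching edges at basal rates (signal edge excluded from A_base)
  for (e in top$edges) {
    if (isTRUE(e == top$signal_edge)) next
    from <- as.integer(substr(e, 1, 1)); to <- as.integer(substr(e, 2, 2))
    cols <- space_index(space, from, xs)
    add(space_index(space, to, xs), cols, rep(rates$k[[e]], M + 1))
    add(cols, cols, rep(-rates$k[[e]], M + 1))
  }
  # transcription
  leak <- numeric(n)
  for (g in 0:(S - 1)) {
    a <- rates$alpha[g + 1]
    if (a > 0) {
      if (M >= 1) {
        cols <- space_index(space, g, 0:(M - 1))
        add(space_index(space, g, 1:M), cols, rep(a, M))
        add(cols, cols, rep(-a, M))
      }
      if (!reflect_top) {
        topcol <- space_index(space, g, M)
        add(topcol, topcol, -a)
        leak[topcol] <- a
      }
    }
  }
  # degradation
  for (g in 0:(S - 1)) {
    if (M >= 1) {
      cols <- space_index(space, g, 1:M)
      add(space_index(space, g, 0:(M - 1)), cols, rates$delta * (1:M))
      add(cols, cols, -rates$delta * (1:M))
    }
  }
  # unit-rate generator of the signal edge
  se <- top$signal_edge
  if (top$signal_mode == "none") {
    ei <- integer(0); ej <- integer(0); ev <- numeric(0)
  } else {
    from <- as.integer(substr(se, 1, 1)); to <- as.integer(substr(se, 2, 2))
    cols <- space_index(space, from, xs)
    ei <- c(space_index(space, to, xs), cols)
    ej <- c(cols, cols)
    ev <- c(rep(1, M + 1), rep(-1, M + 1))
  }

  sig <- list(
    mode = sig_mode_code(top$signal_mode, suppress_form),
    k = if (top$signal_mode == "none") 0 else unname(rates$k[[se]]),
    b = rates$b,
    r1 = sp$r1, r2 = sp$r2,
    use_table = !is.null(signal_table),
    table_times = if (is.null(signal_table)) numeric(0) else signal_table$times,
    table_values = if (is.null(signal_table)) numeric(0) else signal_table$values
  )
  structure(list(leak = leak, sig = sig,
                 space = space, alpha = rates$alpha, delta = rates$delta,
                 reflect_top = reflect_top,
                 base_trip = list(i = ti, j = tj, x = tv),
                 e_trip = list(i = ei, j = ej, x = ev)),
            class = "sigburst_generator")
}

signal_edge_rate_at <- function(sig, t) {
  s <- if (sig$use_table) {
    idx <- findInterval(t, sig$table_times)
    sig$table_values[pmax(idx, 1)]
  } else {
    exp(-sig$r1 * t) * (1 - exp(-sig$r2 * t))
  }
  switch(as.character(sig$mode),
    "0" = rep(sig$k, length(t)),
    "1" = sig$k + sig$b * s,
    "2" = sig$k / (1 + sig$b * s),
    "3" = sig$k * pmax(0, 1 - sig$b * s))
}

#' @describeIn build_generator The full sparse rate matrix `A(t)` frozen at
#'   time `t` (off-diagonals >= 0, column sums <= 0).
#' @param gen A `sigburst_generator`.
#' @param t Time in seconds.
#' @export
generator_matrix <- function(gen, t) {
  stopifnot(inherits(gen, "sigburst_generator"))
  kt <- signal_edge_rate_at(gen$sig, t)
  n <- gen$space$dim
  Matrix::sparseMatrix(i = c(gen$base_trip$i, gen$e_trip$i),
    j = c(gen$base_trip$j, gen$e_trip$j),
    x = c(gen$base_trip$x, kt * gen$e_trip$x), dims = c(n, n))
}

fsp_integrate <- function(gen, p0, times, rtol, atol) {
  fsp_integrate_cpp(gen$space$dim,
    as.integer(gen$base_trip$i), as.integer(gen$base_trip$j), gen$base_trip$x,
    as.integer(gen$e_trip$i), as.integer(gen$e_trip$j), gen$e_trip$x,
    gen$leak, gen$sig, p0, times, rtol, atol)
}

#' Stationary distribution of the signal-free model
#'
#' Solves `A p = 0` with the signal held at zero and the condition's
#' substituted constants, on a reflecting truncated space. The gene-state
#' marginal equals the analytic birth-death stationary vector with
#' `pi[i+1]/pi[i] = k_up/k_down`.
#'
#' @inheritParams build_generator
#' @param max_count Truncation bound; expanded automatically until the mass
#'   in the top 5% of counts is below `tail_tol` (set `tail_tol = Inf` to
#'   accept the truncated law as-is, e.g. under censored fitting).
#' @param tail_tol Acceptable probability mass near the boundary.
#' @return Numeric probability vector over (gene state, count), flat index
#'   `state + n_states * count + 1`, with attributes `space`.
#' @export
stationary_distribution <- function(gene, condition, sp,
                                    max_count = 256,
                                    suppress_form = c("saturating", "linear"),
                                    tail_tol = 1e-10, max_count_ceiling = 8192) {
  suppress_form <- match.arg(suppress_form)
  rates <- condition_rates(gene, condition)
  if (all(rates$alpha == 0) && all(rates$k == 0)) {
    rlang::abort("degenerate chain: all rates zero",
      class = "sigburst_error_config")
  }
  M <- max_count
  repeat {
    space <- state_space(gene$topology$n_states, M)
    gen <- build_generator(gene, condition, space, sp,
      suppress_form = suppress_form,
      signal_table = list(times = 0, values = 0), reflect_top = TRUE)
    # shifted inverse iteration with a banded LU (half-bandwidth n_states):
    # the null vector is amplified by ~1/shift per solve, so two iterations
    # reach roundoff; the shifted matrix is column diagonally dominant, so
    # no pivoting is needed and the band never fills in
    k0 <- signal_edge_rate_at(gen$sig, 0)
    ti <- c(gen$base_trip$i, gen$e_trip$i)
    tj <- c(gen$base_trip$j, gen$e_trip$j)
    tv <- c(gen$base_trip$x, k0 * gen$e_trip$x)
    shift <- 1e-8 * max(abs(tv))
    p <- stationary_banded_cpp(space$dim, space$n_states,
      as.integer(ti), as.integer(tj), tv, shift, 2L)
    tail_mass <- sum(marginal_from_prob(p, space)[(floor(0.95 * M) + 1):(M + 1)])
    if (tail_mass <= tail_tol || M >= max_count_ceiling) {
      if (tail_mass > tail_tol) {
        rlang::abort(sprintf(
          "stationary tail mass %.3g above tolerance at the ceiling max_count %d",
          tail_mass, M), class = "sigburst_error_truncation")
      }
      attr(p, "space") <- space
      return(p)
    }
    M <- min(2L * M, max_count_ceiling)
  }
}

marginal_from_prob <- function(p, space) {
  colSums(matrix(p, nrow = space$n_states))
}

pad_distribution <- function(p, space_from, space_to) {
  stopifnot(space_from$n_states == space_to$n_states)
  out <- numeric(space_to$dim)
  keep <- min(space_from$dim, space_to$dim)
  out[seq_len(keep)] <- p[seq_len(keep)]
  out
}

#' Solve the chemical master equation by finite state projection
#'
#' Integrates `dp/dt = A(t) p` for one gene under one inhibitor condition on
#' a truncated (gene state x mRNA count) space with an absorbing truncation
#' sink. If the final sink mass exceeds `tol`, `max_count` is doubled and
#' the integration restarted, up to `max_count_ceiling`.
#'
#' @inheritParams build_generator
#' @param times Output times in seconds, strictly increasing, starting at 0.
#' @param init Initial distribution over the space (flat vector), or `NULL`
#'   to use the signal-free stationary distribution computed with this
#'   condition's substituted constants (set `init_condition = "none"` for
#'   the drug-free stationary law instead).
#' @param tol Acceptable final sink mass (truncation-error certificate).
#' @param max_count Initial truncation bound.
#' @param max_count_ceiling Largest truncation bound tried.
#' @param expand If `FALSE`, the space is never expanded: the truncated
#'   solution is returned whatever the sink mass, for use with consistent
#'   top-bin censoring (the fitting objective); `tol` is then ignored.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param init_condition Condition whose stationary law initializes the
#'   solve when `init` is `NULL`; defaults to `condition`.
#' @return A `sigburst_fsp` object: `times`, `prob` (dim x time matrix),
#'   `sink_mass`, `space`, `alpha`, and a `diagnostics` list (expansions,
#'   final dimension, achieved sink mass).
#' @export
fsp_solve <- function(gene, condition, sp, times, init = NULL, tol = 1e-4,
                      max_count = 1500, max_count_ceiling = 8192,
                      rtol = 1e-8, atol = 1e-12,
                      suppress_form = c("saturating", "linear"),
                      signal_table = NULL, init_condition = condition,
                      expand = TRUE) {
  suppress_form <- match.arg(suppress_form)
  stopifnot(length(times) >= 1, all(diff(times) > 0), times[1] >= 0)
  if (times[1] != 0) times <- c(0, times)
  if (!is.null(init) && abs(sum(init) - 1) > 1e-9) {
    rlang::abort("init must sum to 1 within 1e-9", class = "sigburst_error_config")
  }
  M <- max_count
  if (!expand) {
    max_count_ceiling <- M
    tol <- Inf
  }
  expansions <- 0L
  repeat {
    if (is.null(init)) {
      p0 <- stationary_distribution(gene, init_condition, sp, max_count = M,
        suppress_form = suppress_form, max_count_ceiling = max_count_ceiling,
        tail_tol = if (expand) 1e-10 else Inf)
      # the stationary solve may have needed a larger space; never truncate
      # its mass away -- grow the solve space with it
      if (attr(p0, "space")$max_count > M) {
        M <- attr(p0, "space")$max_count
        expansions <- expansions + 1L
      }
      space <- state_space(gene$topology$n_states, M)
      p0 <- pad_distribution(p0, attr(p0, "space"), space)
    } else {
      space <- state_space(gene$topology$n_states, M)
      if (length(init) > space$dim) {
        rlang::abort("init longer than the state space",
          class = "sigburst_error_config")
      }
      p0 <- pad_distribution(init,
        state_space(space$n_states, length(init) / space$n_states - 1L), space)
    }
    gen <- build_generator(gene, condition, space, sp,
      suppress_form = suppress_form, signal_table = signal_table)
    res <- fsp_integrate(gen, p0, times, rtol, atol)
    sink <- res$sink
    # integrator roundoff can leave O(atol) negative entries; clamp them
    res$prob[res$prob < 0 & res$prob > -1e-8] <- 0
    if (sink[length(sink)] <= tol) {
      return(structure(list(
        times = times, prob = res$prob, sink_mass = sink, space = space,
        alpha = gen$alpha, condition = condition,
        diagnostics = list(expansions = expansions, dim = space$dim,
          max_count = space$max_count, final_sink = sink[length(sink)],
          tol = tol)),
        class = "sigburst_fsp"))
    }
    if (M >= max_count_ceiling) {
      rlang::abort(sprintf(
        "FSP truncation failure: sink mass %.3g > tol %.3g at ceiling max_count %d",
        sink[length(sink)], tol, M), class = "sigburst_error_truncation")
    }
    M <- min(2L * M, max_count_ceiling)
    expansions <- expansions + 1L
  }
}

#' @export
print.sigburst_fsp <- function(x, ...) {
  cat(sprintf(
    "<sigburst_fsp> %d states x counts 0..%d, %d times, final sink %.2e\n",
    x$space$n_states, x$space$max_count, length(x$times),
    x$diagnostics$final_sink))
  invisible(x)
}

# internal: (max_count+1) x T matrix of mRNA marginals
marginal_matrix <- function(sol) {
  S <- sol$space$n_states
  apply(sol$prob, 2, function(p) colSums(matrix(p, nrow = S)))
}

#' mRNA copy-number marginal of an FSP solution
#'
#' Sums the joint law over gene states; each marginal sums to
#' `1 - sink_mass(t)`.
#'
#' @param sol A `sigburst_fsp` from [fsp_solve()].
#' @return Tibble with columns `time_s`, `count`, `probability`.
#' @export
marginal_mrna <- function(sol) {
  stopifnot(inherits(sol, "sigburst_fsp"))
  m <- marginal_matrix(sol)
  tidyr::expand_grid(time_s = sol$times, count = 0:sol$space$max_count) |>
    dplyr::arrange(.data$time_s, .data$count) |>
    dplyr::mutate(probability = as.vector(m))
}

#' Gene-state occupancy over time
#'
#' @inheritParams marginal_mrna
#' @return Tibble with columns `time_s`, `state` (`G0`, `G1`, ...),
#'   `probability`; per time the occupancies sum to `1 - sink_mass(t)`.
#' @export
state_occupancy <- function(sol) {
  stopifnot(inherits(sol, "sigburst_fsp"))
  S <- sol$space$n_states
  occ <- apply(sol$prob, 2, function(p) rowSums(matrix(p, nrow = S)))
  tidyr::expand_grid(time_s = sol$times, state = paste0("G", 0:(S - 1))) |>
    dplyr::arrange(.data$time_s, .data$state) |>
    dplyr::mutate(probability = as.vector(occ))
}

#' Mean instantaneous transcription rate over time
#'
#' `sum_i alpha_i P(G_i)(t)`, molecules per second.
#'
#' @inheritParams marginal_mrna
#' @return Tibble with columns `time_s`, `rate`.
#' @export
mean_transcription_rate <- function(sol) {
  stopifnot(inherits(sol, "sigburst_fsp"))
  S <- sol$space$n_states
  occ <- apply(sol$prob, 2, function(p) rowSums(matrix(p, nrow = S)))
  tibble::tibble(time_s = sol$times,
    rate = as.numeric(crossprod(occ, sol$alpha)))
}

#' Mean and standard deviation of the mRNA copy number over time
#'
#' Computed on the sink-renormalized marginal.
#'
#' @inheritParams marginal_mrna
#' @return Tibble with columns `time_s`, `mean`, `sd`.
#' @export
fsp_moments <- function(sol) {
  stopifnot(inherits(sol, "sigburst_fsp"))
  m <- marginal_matrix(sol)
  xs <- 0:sol$space$max_count
  purrr::map_dfr(seq_along(sol$times), function(j) {
    q <- m[, j] / sum(m[, j])
    mu <- sum(xs * q)
    tibble::tibble(time_s = sol$times[j], mean = mu,
      sd = sqrt(max(0, sum(xs^2 * q) - mu^2)))
  })
}

#' Export an FSP solution as TSV + JSON diagnostics
#'
#' Writes `<prefix>_marginal.tsv` (columns `time_s`, `state_or_count`,
#' `probability`, the mRNA marginal), `<prefix>_occupancy.tsv` (gene-state
#' occupancy) and `<prefix>_diagnostics.json` (sink mass per time, dimension,
#' expansions).
#'
#' @inheritParams marginal_mrna
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
export_fsp_solution <- function(sol, prefix) {
  stopifnot(inherits(sol, "sigburst_fsp"))
  marg <- marginal_mrna(sol) |> dplyr::rename(state_or_count = "count")
  occ <- state_occupancy(sol) |> dplyr::rename(state_or_count = "state")
  paths <- paste0(prefix, c("_marginal.tsv", "_occupancy.tsv",
    "_diagnostics.json"))
  utils::write.table(marg, paths[1], sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(occ, paths[2], sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(list(times = sol$times, sink_mass = sol$sink_mass,
    dim = sol$space$dim, max_count = sol$space$max_count,
    expansions = sol$diagnostics$expansions, tol = sol$diagnostics$tol),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
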