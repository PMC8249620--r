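#' Inhibitor conditions of the experimental design
#'
#' The four inhibitor conditions under which cells are measured after LPS
#' stimulation. Models are calibrated on the three training conditions and
#' evaluated on the held-out combined-drug condition.
#'
#' @return Character vector of condition labels.
#' @export
conditions <- function() c("none", "mg132", "u0126", "both")

#' @rdname conditions
#' @export
training_conditions <- function() c("none", "mg132", "u0126")

#' @rdname conditions
#' @export
test_conditions <- function() "both"

assert_condition <- function(condition) {
  if (!is.character(condition) || !all(condition %in% conditions())) {
    rlang::abort(
      paste0("`condition` must be one of: ", paste(conditions(), collapse = ", ")),
      class = "sigburst_error_condition"
    )
  }
  condition
}

#' Nuclear NF-kB signal parameters
#'
#' The nuclear NF-kB abundance after LPS stimulation is described
#' phenomenologically by \eqn{s(t) = e^{-r_1 t}(1 - e^{-r_2 t})}: a rapid rise
#' (rate `r2`) followed by a slower decay (rate `r1`), in arbitrary units.
#' The signal is shared by all genes of a combinatorial model.
#'
#' @param r1 Decay rate, per second; must be positive.
#' @param r2 Rise rate, per second; must be positive.
#' @return A `sigburst_signal` object.
#' @examples
#' sp <- signal_params(r1 = 9.01e-4, r2 = 3.05e-4)
#' signal_peak_time(sp) / 60  # minutes
#' @export
signal_params <- function(r1, r2) {
  stopifnot(is.numeric(r1), is.numeric(r2), length(r1) == 1, length(r2) == 1)
  if (!is.finite(r1) || !is.finite(r2) || r1 <= 0 || r2 <= 0) {
    rlang::abort("signal rates r1 and r2 must be finite and > 0",
      class = "sigburst_error_domain")
  }
  structure(list(r1 = r1, r2 = r2), class = "sigburst_signal")
}

#' Evaluate the nuclear NF-kB signal
#'
#' @param t Time(s) in seconds since LPS stimulation; non-negative.
#' @param sp A [signal_params()] object.
#' @return Signal value(s) in `[0, 1)` (arbitrary units; not rescaled to a
#'   unit peak).
#' @export
nfkb_signal <- function(t, sp) {
  stopifnot(inherits(sp, "sigburst_signal"))
  if (any(t < 0)) {
    rlang::abort("signal time `t` must be >= 0", class = "sigburst_error_domain")
  }
  exp(-sp$r1 * t) * (1 - exp(-sp$r2 * t))
}

#' @describeIn nfkb_signal Analytic time of the signal maximum,
#'   \eqn{t^* = \ln(1 + r_2/r_1)/r_2}, in seconds.
#' @export
signal_peak_time <- function(sp) {
  stopifnot(inherits(sp, "sigburst_signal"))
  log(1 + sp$r2 / sp$r1) / sp$r2
}

edge_names <- function(n_states) {
  up <- paste0(seq_len(n_states - 1) - 1, seq_len(n_states - 1))
  down <- paste0(seq_len(n_states - 1), seq_len(n_states - 1) - 1)
  c(rbind(up, down))
}

#' Gene-state network topology
#'
#' A gene switches among 2 or 3 promoter states arranged as a birth-death
#' chain (only adjacent states connected). Exactly one transition is
#' modulated by the NF-kB signal: in `enhance` mode the signal adds to an
#' activating (upward) rate, in `suppress` mode it divides a deactivating
#' (downward) rate.
#'
#' @param n_states Number of gene states, 2 or 3 (1 gives a constitutive,
#'   signal-free gene, useful as an analytic reference).
#' @param signal_edge Edge label (`"01"`, `"10"`, `"12"`, `"21"`) of the
#'   signal-modulated transition, or `NULL` for none.
#' @param signal_mode `"enhance"`, `"suppress"`, or `"none"`.
#' @param name Optional short label; generated when missing.
#' @return A `sigburst_topology` object.
#' @export
gene_topology <- function(n_states, signal_edge = NULL,
                          signal_mode = c("enhance", "suppress", "none"),
                          name = NULL) {
  stopifnot(n_states %in% c(1L, 2L, 3L))
  signal_mode <- match.arg(signal_mode)
  if (n_states == 1L || is.null(signal_edge)) {
    signal_mode <- "none"
    return(structure(
      list(n_states = as.integer(n_states),
           states = paste0("G", 0:(n_states - 1)),
           edges = if (n_states > 1) edge_names(n_states) else character(0),
           signal_edge = NA_character_, signal_mode = "none",
           name = name %||% sprintf("%ds_const", n_states)),
      class = "sigburst_topology"))
  }
  edges <- edge_names(n_states)
  if (!signal_edge %in% edges) {
    rlang::abort(sprintf("signal_edge '%s' is not an edge of a %d-state chain",
      signal_edge, n_states), class = "sigburst_error_config")
  }
  up_edge <- substr(signal_edge, 1, 1) < substr(signal_edge, 2, 2)
  if (signal_mode == "enhance" && !up_edge) {
    rlang::abort("enhance mode modulates an activating (upward) edge",
      class = "sigburst_error_config")
  }
  if (signal_mode == "suppress" && up_edge) {
    rlang::abort("suppress mode modulates a deactivating (downward) edge",
      class = "sigburst_error_config")
  }
  if (is.null(name)) {
    name <- sprintf("%ds_%s%s", n_states,
      if (signal_mode == "enhance") "act" else "sup", signal_edge)
  }
  structure(
    list(n_states = as.integer(n_states), states = paste0("G", 0:(n_states - 1)),
         edges = edges, signal_edge = signal_edge, signal_mode = signal_mode,
         name = name),
    class = "sigburst_topology"
  )
}

#' Enumerate the candidate single-gene mechanisms
#'
#' The screened mechanism family: two 2-state variants (signal enhances
#' G0->G1, or suppresses G1->G0) and four 3-state variants (signal enhances
#' G0->G1 or G1->G2, or suppresses G1->G0 or G2->G1). Each has exactly one
#' signal-modulated edge.
#'
#' @return Named list of six [gene_topology()] objects.
#' @export
enumerate_single_gene_topologies <- function() {
  tops <- list(
    gene_topology(2, "01", "enhance"),
    gene_topology(2, "10", "suppress"),
    gene_topology(3, "01", "enhance"),
    gene_topology(3, "12", "enhance"),
    gene_topology(3, "10", "suppress"),
    gene_topology(3, "21", "suppress")
  )
  rlang::set_names(tops, purrr::map_chr(tops, "name"))
}

#' Kinetic rate parameters of a single gene
#'
#' @param topology A [gene_topology()].
#' @param k Named numeric vector of basal switching rates (per second), one
#'   per edge of the chain (e.g. `c("01" = ..., "10" = ..., "12" = ...,
#'   "21" = ...)` for 3 states).
#' @param b Signal coefficient of the signal edge: per second in enhance
#'   mode (`k + b s(t)`), dimensionless in suppress mode
#'   (`k / (1 + b s(t))`).
#' @param alpha Transcription rates, molecules per second, one per state.
#' @param delta First-order mRNA degradation rate constant, per second
#'   (degradation propensity `delta * x`).
#' @return A `sigburst_rates` object.
#' @export
gene_rates <- function(topology, k = numeric(), b = 0, alpha, delta) {
  stopifnot(inherits(topology, "sigburst_topology"))
  k <- if (length(topology$edges)) k[topology$edges] else numeric()
  if (anyNA(k) || any(k < 0)) {
    rlang::abort("all edges of the chain need a basal rate >= 0",
      class = "sigburst_error_config")
  }
  names(k) <- topology$edges
  stopifnot(is.numeric(b), length(b) == 1, b >= 0)
  if (length(alpha) != topology$n_states || any(alpha < 0)) {
    rlang::abort("alpha needs one non-negative entry per gene state",
      class = "sigburst_error_config")
  }
  if (!is.numeric(delta) || delta <= 0) {
    rlang::abort("delta must be > 0", class = "sigburst_error_config")
  }
  structure(list(k = k, b = b, alpha = as.numeric(alpha), delta = delta),
    class = "sigburst_rates")
}

#' Inhibitor parameter substitutions
#'
#' MG132 (proteasome inhibitor blocking NF-kB signalling) is modeled as a
#' reduction of the signal coefficient `b`; U0126 (MEK inhibitor blocking
#' C/EBP) as a reduction of the basal activation rate `k01` into which the
#' constant C/EBP influence is absorbed. The combined condition applies both
#' substitutions; the substituted parameter sets are disjoint, so the order
#' is immaterial.
#'
#' @param b_mg132 MG132-substituted value of the signal coefficient `b`.
#' @param k01_u0126 U0126-substituted value of `k01`.
#' @return A `sigburst_inhibitors` object.
#' @export
inhibitor_map <- function(b_mg132, k01_u0126) {
  stopifnot(is.numeric(b_mg132), b_mg132 >= 0, is.numeric(k01_u0126),
    k01_u0126 >= 0)
  structure(list(mg132 = list(b = b_mg132), u0126 = list(k01 = k01_u0126)),
    class = "sigburst_inhibitors")
}

#' A single gene model (topology + rates + inhibitor substitutions)
#'
#' @param topology A [gene_topology()].
#' @param rates A [gene_rates()].
#' @param inhibitors An [inhibitor_map()], or `NULL` if only the
#'   inhibitor-free condition will be used.
#' @return A `sigburst_gene` object.
#' @export
gene_model <- function(topology, rates, inhibitors = NULL) {
  stopifnot(inherits(topology, "sigburst_topology"),
    inherits(rates, "sigburst_rates"))
  if (!is.null(inhibitors)) stopifnot(inherits(inhibitors, "sigburst_inhibitors"))
  structure(list(topology = topology, rates = rates, inhibitors = inhibitors),
    class = "sigburst_gene")
}

#' Apply an inhibitor condition to a gene's constants
#'
#' Returns the gene's rate constants after the condition's substitutions:
#' MG132 replaces `b`, U0126 replaces `k01`; `both` applies both, `none`
#' neither.
#'
#' @param gene A [gene_model()].
#' @param condition One of [conditions()].
#' @return A `sigburst_rates` object with substitutions applied.
#' @export
condition_rates <- function(gene, condition) {
  stopifnot(inherits(gene, "sigburst_gene"))
  assert_condition(condition)
  rates <- gene$rates
  if (condition == "none") return(rates)
  im <- gene$inhibitors
  if (is.null(im)) {
    rlang::abort(sprintf("condition '%s' requested but the gene has no inhibitor map",
      condition), class = "sigburst_error_config")
  }
  if (condition %in% c("mg132", "both")) rates$b <- im$mg132$b
  if (condition %in% c("u0126", "both")) rates$k["01"] <- im$u0126$k01
  rates
}

signal_edge_rate <- function(k_edge, b, s, mode, suppress_form = "saturating") {
  if (mode == "enhance") {
    k_edge + b * s
  } else if (suppress_form == "saturating") {
    k_edge / (1 + b * s)
  } else {
    k_edge * pmax(0, 1 - b * s)
  }
}

#' Instantaneous reaction rates of a gene under a condition
#'
#' Evaluates all edge switching rates and state transcription rates at time
#' `t` under an inhibitor condition. Non-signal edges keep their basal rate;
#' the signal edge is `k + b_eff s(t)` in enhance mode and
#' `k / (1 + b_eff s(t))` in suppress mode (default `suppress_form
#' = "saturating"`, guaranteed positive; `"linear"` gives
#' `k max(0, 1 - b_eff s(t))`).
#'
#' @inheritParams condition_rates
#' @param sp A [signal_params()].
#' @param t Time in seconds, non-negative (vectorized).
#' @param suppress_form `"saturating"` (default) or `"linear"`.
#' @return A tibble with one row per `t`: columns `time_s`, one column per
#'   edge (`k01`, `k10`, ...) and per state (`alpha0`, ...), and `delta`.
#' @export
effective_rates <- function(gene, condition, sp, t,
                            suppress_form = c("saturating", "linear")) {
  suppress_form <- match.arg(suppress_form)
  rates <- condition_rates(gene, condition)
  top <- gene$topology
  s <- nfkb_signal(t, sp)
  out <- tibble::tibble(time_s = t)
  for (e in top$edges) {
    val <- if (isTRUE(e == top$signal_edge)) {
      signal_edge_rate(rates$k[[e]], rates$b, s, top$signal_mode, suppress_form)
    } else {
      rep(rates$k[[e]], length(t))
    }
    out[[paste0("k", e)]] <- val
  }
  for (i in seq_len(top$n_states)) {
    out[[paste0("alpha", i - 1)]] <- rep(rates$alpha[i], length(t))
  }
  out$delta <- rates$delta
  out
}

#' Combinatorial two-gene model
#'
#' Couples one gene model per gene (IL-1 beta, TNF-alpha) through a shared
#' time-varying NF-kB signal. The genes are conditionally independent given
#' the signal: they share `signal` but are otherwise parameter-disjoint.
#'
#' @param name Model label, e.g. `"CM1"`.
#' @param signal A [signal_params()] shared by both genes.
#' @param genes Named list of [gene_model()] objects (canonically `il1b`,
#'   `tnfa`).
#' @return A `sigburst_model` object.
#' @export
combinatorial_model <- function(name, signal, genes) {
  stopifnot(inherits(signal, "sigburst_signal"), is.list(genes),
    length(genes) >= 1, !is.null(names(genes)))
  purrr::walk(genes, function(g) stopifnot(inherits(g, "sigburst_gene")))
  structure(list(name = name, signal = signal, genes = genes),
    class = "sigburst_model")
}

#' @export
print.sigburst_model <- function(x, ...) {
  cat(sprintf("<sigburst_model> %s\n", x$name))
  cat(sprintf("  signal: r1 = %.3g /s, r2 = %.3g /s (peak at %.1f min)\n",
    x$signal$r1, x$signal$r2, signal_peak_time(x$signal) / 60))
  for (g in names(x$genes)) {
    top <- x$genes[[g]]$topology
    cat(sprintf("  %s: %d states, signal %ss edge %s\n", g, top$n_states,
      top$signal_mode, top$signal_edge))
  }
  invisible(x)
}

default_gene_rates <- function(topology) {
  k <- rlang::set_names(rep(1e-3, length(topology$edges)), topology$edges)
  gene_rates(topology, k = k, b = 1e-2,
    alpha = c(1e-4, 0.05, 0.1)[seq_len(topology$n_states)], delta = 2e-4)
}

#' Enumerate combinatorial two-gene models
#'
#' Cartesian product of per-gene topology lists: a list of topologies per
#' gene gives one combinatorial model per pair, all sharing one signal.
#' With 3 topologies per gene this yields the 9-model screen; with all 6,
#' the full 36-model family.
#'
#' @param topologies Named list (one entry per gene) of lists of
#'   [gene_topology()] objects.
#' @param signal Shared [signal_params()].
#' @param rates Optional named list (per gene) of functions
#'   `function(topology)` returning initial [gene_rates()]; defaults to
#'   generic starting values meant to seed a fit.
#' @param inhibitors Optional named list (per gene) of [inhibitor_map()]s.
#' @return Named list of [combinatorial_model()] objects with deterministic
#'   names `<gene1 topology>__<gene2 topology>`.
#' @export
enumerate_combinatorial_models <- function(topologies, signal, rates = NULL,
                                           inhibitors = NULL) {
  stopifnot(is.list(topologies), !is.null(names(topologies)))
  if (any(purrr::map_int(topologies, length) == 0)) {
    rlang::abort("every gene needs at least one topology",
      class = "sigburst_error_config")
  }
  gene_names <- names(topologies)
  grid <- expand.grid(purrr::map(topologies, seq_along), KEEP.OUT.ATTRS = FALSE)
  models <- purrr::pmap(grid, function(...) {
    idx <- list(...)
    genes <- purrr::map(gene_names, function(g) {
      top <- topologies[[g]][[idx[[g]]]]
      r <- if (!is.null(rates) && !is.null(rates[[g]])) rates[[g]](top) else
        default_gene_rates(top)
      gene_model(top, r, inhibitors = inhibitors[[g]])
    })
    names(genes) <- gene_names
    nm <- paste(purrr::map_chr(genes, function(g) g$topology$name),
      collapse = "__")
    combinatorial_model(nm, signal, genes)
  })
  rlang::set_names(models, purrr::map_chr(models, "name"))
}
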