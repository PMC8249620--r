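#' Bayesian Information Criterion
#'
#' `n_params * log(n_obs) - 2 * loglik`; lower is better. `n_obs` is the
#' total number of cells across all training (gene, condition, time)
#' samples.
#'
#' @param loglik Training log-likelihood (nats).
#' @param n_params Number of free parameters.
#' @param n_obs Number of observations (>= 1).
#' @return BIC value.
#' @export
bic <- function(loglik, n_params, n_obs) {
  stopifnot(n_obs >= 1, n_params >= 0)
  n_params * log(n_obs) - 2 * loglik
}

as_sigburst_model <- function(x) {
  if (inherits(x, "sigburst_fit")) x$model
  else if (inherits(x, "sigburst_model")) x
  else rlang::abort("expected a sigburst_model or sigburst_fit",
    class = "sigburst_error_config")
}

#' Rank fitted models by fit + held-out prediction
#'
#' Scores every fit on the held-out combined-inhibitor data (parameters
#' unchanged, no refitting) and ranks by the combined score
#' `loglik_train + loglik_test`, descending; ties broken by lower BIC, then
#' by model name.
#'
#' @param fits List of `sigburst_fit` objects.
#' @param test_table Count table containing the `both` condition only (or a
#'   table from which the `both` rows are taken).
#' @return Tibble with columns `model`, `loglik_train`, `bic`,
#'   `loglik_test`, `score`, ordered best first.
#' @export
rank_models <- function(fits, test_table) {
  stopifnot(length(fits) >= 1)
  if (!"both" %in% unique(test_table$condition)) {
    rlang::abort("test table must contain the combined ('both') condition",
      class = "sigburst_error_config")
  }
  test_table <- dplyr::filter(test_table, .data$condition == "both")
  scores <- purrr::map_dfr(fits, function(fit) {
    stopifnot(inherits(fit, "sigburst_fit"))
    ll_test <- dataset_loglik(test_table, fit$model, conds = "both",
      fsp_args = fit$fsp_args)
    tibble::tibble(model = fit$model$name, loglik_train = fit$loglik,
      bic = bic(fit$loglik, fit$n_params, fit$n_obs), loglik_test = ll_test,
      score = fit$loglik + ll_test)
  })
  dplyr::arrange(scores, dplyr::desc(.data$score), .data$bic, .data$model)
}

#' Predict the combined-inhibitor condition from single-drug fits
#'
#' Solves the FSP under the `both` condition — MG132 and U0126 parameter
#' substitutions active simultaneously — at the requested times, with no
#' parameter re-estimated. A pure function of the fit's stored estimates.
#'
#' @param fit A `sigburst_fit` (or a [combinatorial_model()] with inhibitor
#'   maps).
#' @param times Prediction times in seconds.
#' @param fsp_args Extra arguments for [fsp_solve()].
#' @return A `sigburst_prediction`: tibbles `distributions` (per gene and
#'   time, renormalized predicted marginals) and `moments` (predicted mean
#'   and SD per gene and time).
#' @export
predict_combined <- function(fit, times = c(0, 1800, 3600, 7200, 14400),
                             fsp_args = list()) {
  model <- as_sigburst_model(fit)
  missing_inh <- purrr::map_lgl(model$genes, function(g) is.null(g$inhibitors))
  if (any(missing_inh)) {
    rlang::abort(paste0("gene(s) without MG132/U0126 substitutions: ",
      paste(names(model$genes)[missing_inh], collapse = ", ")),
      class = "sigburst_error_config")
  }
  if (inherits(fit, "sigburst_fit") && is.null(fsp_args$max_count)) {
    fsp_args <- utils::modifyList(fit$fsp_args, fsp_args)
    # prediction is reported with the certified (adaptively expanded) solve
    # even when the fit itself used a fixed censored truncation
    fsp_args$expand <- NULL
  }
  sols <- purrr::map(model$genes, function(g) {
    do.call(fsp_solve, c(list(gene = g, condition = "both", sp = model$signal,
      times = times), fsp_args))
  })
  dists <- purrr::imap_dfr(sols, function(sol, g) {
    marginal_mrna(sol) |>
      dplyr::group_by(.data$time_s) |>
      dplyr::mutate(probability = .data$probability / sum(.data$probability)) |>
      dplyr::ungroup() |>
      dplyr::mutate(gene = g, .before = 1)
  })
  moments <- purrr::imap_dfr(sols, function(sol, g) {
    dplyr::mutate(fsp_moments(sol), gene = g, .before = 1)
  })
  structure(list(model = model$name, condition = "both",
    distributions = dists, moments = moments),
    class = "sigburst_prediction")
}

#' @export
print.sigburst_prediction <- function(x, ...) {
  cat(sprintf("<sigburst_prediction> %s under combined inhibitors\n", x$model))
  print(x$moments)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sigburst_prediction <- function(x, ...) x$moments

#' Export a prediction report as JSON + per-time TSV distributions
#'
#' @param pred A `sigburst_prediction`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_prediction <- function(pred, prefix) {
  stopifnot(inherits(pred, "sigburst_prediction"))
  paths <- paste0(prefix, c("_prediction.json", "_distributions.tsv"))
  jsonlite::write_json(list(model = pred$model, condition = pred$condition,
    moments = pred$moments), paths[1], auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.table(pred$distributions, paths[2], sep = "\t",
    row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Headline rate-constant ratios of a fitted model
#'
#' Per gene: basal deactivation over activation `k10/k01`, the
#' active-state exit over entry `k21/k12` (3-state genes), the MG132
#' reduction of the signal coefficient `b/b_mg132`, and the U0126 reduction
#' of the basal activation `k01/k01_u0126`. With a second model, also the
#' relative difference of the degradation rates
#' `|delta_1 - delta_2| / delta_1` per gene. Values come from the stored
#' estimates only.
#'
#' @param fit A `sigburst_fit` or [combinatorial_model()].
#' @param other Optional second fit/model for the degradation comparison.
#' @return Tibble with columns `model`, `gene`, `ratio`, `value`.
#' @export
summarize_rates <- function(fit, other = NULL) {
  model <- as_sigburst_model(fit)
  out <- purrr::imap_dfr(model$genes, function(g, nm) {
    r <- g$rates
    rows <- tibble::tibble(
      gene = nm,
      ratio = c("k10/k01", "b/b_mg132", "k01/k01_u0126"),
      value = c(
        unname(r$k[["10"]] / r$k[["01"]]),
        if (is.null(g$inhibitors)) NA_real_ else r$b / g$inhibitors$mg132$b,
        if (is.null(g$inhibitors)) NA_real_ else
          unname(r$k[["01"]]) / g$inhibitors$u0126$k01))
    if (g$topology$n_states >= 3) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(gene = nm,
        ratio = "k21/k12", value = unname(r$k[["21"]] / r$k[["12"]])))
    }
    rows
  })
  out <- dplyr::mutate(out, model = model$name, .before = 1)
  if (!is.null(other)) {
    other_model <- as_sigburst_model(other)
    shared <- intersect(names(model$genes), names(other_model$genes))
    dd <- purrr::map_dfr(shared, function(nm) {
      d1 <- model$genes[[nm]]$rates$delta
      d2 <- other_model$genes[[nm]]$rates$delta
      tibble::tibble(model = paste(model$name, "vs", other_model$name),
        gene = nm, ratio = "delta_rel_diff", value = abs(d1 - d2) / d1)
    })
    out <- dplyr::bind_rows(out, dd)
  }
  out
}

#' Screen single-gene mechanisms by BIC
#'
#' Fits each candidate topology to one gene's counts under the
#' inhibitor-free condition and ranks by BIC. The default two-stage pipeline
#' keeps the top 3 per gene before the combinatorial fit.
#'
#' @param table Count table.
#' @param gene Gene name.
#' @param topologies List of [gene_topology()] candidates (default all 6).
#' @param signal Starting [signal_params()].
#' @param opt An [opt_config()].
#' @param conds Conditions used for the screen (default inhibitor-free).
#' @return Tibble with `topology`, `loglik`, `n_params`, `bic`, sorted by
#'   BIC, with the fits in the `fit` list-column.
#' @export
screen_single_gene <- function(table, gene,
                               topologies = enumerate_single_gene_topologies(),
                               signal, opt, conds = "none") {
  fits <- purrr::map(topologies, function(top) {
    template <- combinatorial_model(top$name, signal,
      rlang::set_names(list(gene_model(top, default_gene_rates(top))), gene))
    fit_model(template, table, conds = conds, opt = opt)
  })
  tibble::tibble(
    topology = purrr::map_chr(topologies, "name"),
    loglik = purrr::map_dbl(fits, "loglik"),
    n_params = purrr::map_int(fits, "n_params"),
    bic = purrr::map_dbl(fits, function(f) bic(f$loglik, f$n_params, f$n_obs)),
    fit = fits) |>
    dplyr::arrange(.data$bic)
}
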