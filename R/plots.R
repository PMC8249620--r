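#' Plot the NF-kB signal over time
#'
#' @param sp A [signal_params()].
#' @param t_max Largest time shown, seconds.
#' @return A ggplot.
#' @export
plot_signal <- function(sp, t_max = 14400) {
  t <- seq(0, t_max, length.out = 400)
  ggplot2::ggplot(tibble::tibble(time_min = t / 60, signal = nfkb_signal(t, sp)),
    ggplot2::aes(.data$time_min, .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = signal_peak_time(sp) / 60,
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time after LPS (min)", y = "nuclear NF-kB (AU)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigburst_fsp <- function(object, max_count = NULL, ...) {
  marg <- marginal_mrna(object)
  if (!is.null(max_count)) marg <- dplyr::filter(marg, .data$count <= max_count)
  ggplot2::ggplot(marg, ggplot2::aes(.data$count, .data$probability)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~ time_s, scales = "free_y",
      labeller = ggplot2::labeller(time_s = function(x)
        paste0(as.numeric(x) / 60, " min"))) +
    ggplot2::labs(x = "mRNA copies per cell", y = "probability")
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigburst_prediction <- function(object, max_count = NULL, ...) {
  d <- object$distributions
  if (!is.null(max_count)) d <- dplyr::filter(d, .data$count <= max_count)
  ggplot2::ggplot(d, ggplot2::aes(.data$count, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(gene ~ time_s) +
    ggplot2::labs(title = paste(object$model, "prediction, combined inhibitors"),
      x = "mRNA copies per cell", y = "probability")
}

#' Mean/SD trajectories of a model across conditions
#'
#' @param model A [combinatorial_model()] or `sigburst_fit`.
#' @param times Times in seconds.
#' @param conds Conditions to show.
#' @param fsp_args Extra arguments for [fsp_solve()].
#' @return A ggplot of mean mRNA per cell versus time.
#' @export
plot_mean_trajectories <- function(model, times = c(0, 1800, 3600, 7200, 14400),
                                   conds = conditions(), fsp_args = list()) {
  model <- as_sigburst_model(model)
  d <- purrr::imap_dfr(model$genes, function(g, nm) {
    purrr::map_dfr(conds, function(cond) {
      sol <- do.call(fsp_solve, c(list(gene = g, condition = cond,
        sp = model$signal, times = times), fsp_args))
      dplyr::mutate(fsp_moments(sol), gene = nm, condition = cond)
    })
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s / 60, .data$mean,
    colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ gene, scales = "free_y") +
    ggplot2::labs(x = "time after LPS (min)", y = "mean mRNA copies per cell")
}
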