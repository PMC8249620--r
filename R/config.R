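#' Read a combinatorial model from a YAML/JSON config
#'
#' Config layout: `model.name`, `signal.{r1,r2}`, and per gene under
#' `genes.<name>`: `topology.{n_states,signal_edge,signal_mode}`, edge rates
#' `k01,k10[,k12,k21]`, signal coefficient `b`, transcription rates
#' `alpha0..alpha2`, `delta`, and optional
#' `inhibitors.{mg132.b, u0126.k01}` substitution maps.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [combinatorial_model()].
#' @seealso [cm_model()] for the packaged fitted models.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_config(cfg)
}

model_from_config <- function(cfg) {
  sp <- signal_params(cfg$signal$r1, cfg$signal$r2)
  genes <- purrr::imap(cfg$genes, function(g, nm) {
    top <- gene_topology(g$topology$n_states, as.character(g$topology$signal_edge),
      g$topology$signal_mode)
    k <- purrr::map_dbl(top$edges, function(e) {
      v <- g[[paste0("k", e)]]
      if (is.null(v)) rlang::abort(sprintf("gene '%s': missing rate k%s", nm, e),
        class = "sigburst_error_config")
      v
    })
    names(k) <- top$edges
    alpha <- purrr::map_dbl(seq_len(top$n_states) - 1,
      function(i) g[[paste0("alpha", i)]])
    rates <- gene_rates(top, k = k, b = g$b, alpha = alpha, delta = g$delta)
    inh <- NULL
    if (!is.null(g$inhibitors)) {
      inh <- inhibitor_map(b_mg132 = g$inhibitors$mg132$b,
        k01_u0126 = g$inhibitors$u0126$k01)
    }
    gene_model(top, rates, inh)
  })
  combinatorial_model(cfg$model$name, sp, genes)
}

model_to_config <- function(model) {
  genes <- purrr::map(model$genes, function(g) {
    top <- g$topology
    out <- list(topology = list(n_states = top$n_states,
      signal_edge = top$signal_edge, signal_mode = top$signal_mode))
    for (e in top$edges) out[[paste0("k", e)]] <- unname(g$rates$k[[e]])
    out$b <- g$rates$b
    for (i in seq_len(top$n_states)) {
      out[[paste0("alpha", i - 1)]] <- g$rates$alpha[i]
    }
    out$delta <- g$rates$delta
    if (!is.null(g$inhibitors)) {
      out$inhibitors <- list(mg132 = list(b = g$inhibitors$mg132$b),
        u0126 = list(k01 = g$inhibitors$u0126$k01))
    }
    out
  })
  list(model = list(name = model$name),
    signal = list(r1 = model$signal$r1, r2 = model$signal$r2),
    genes = genes)
}

#' Write a combinatorial model to a YAML config
#'
#' @param model A [combinatorial_model()].
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- model_to_config(model)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Packaged fitted combinatorial models CM1 and CM2
#'
#' The two best-performing combinatorial models of LPS-induced IL-1 beta /
#' TNF-alpha transcription, with their published fitted rate constants.
#' Both describe TNF-alpha by a 3-state chain whose G0->G1 activation is
#' enhanced by NF-kB; they differ for IL-1 beta: CM1 lets NF-kB enhance
#' G1->G2, CM2 lets it suppress G1->G0.
#'
#' @param name `"CM1"` or `"CM2"`.
#' @return A [combinatorial_model()].
#' @examples
#' cm_model("CM1")
#' @export
cm_model <- function(name = c("CM1", "CM2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(tolower(name), ".yaml"),
    package = "sigburst", mustWork = TRUE)
  read_model_config(path)
}
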