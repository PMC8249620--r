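#' Kullback-Leibler divergence between count distributions
#'
#' `sum_x p(x) log(p(x)/q(x))` in nats, with `0 log 0 = 0` and the model
#' side floored at `eps` before the ratio so the divergence stays finite
#' when an observed count falls where the model assigns ~0 mass.
#'
#' @param p_emp Empirical probability vector (sums to 1).
#' @param q_model Model probability vector of the same length.
#' @param eps Floor applied to `q_model`.
#' @return Divergence in nats (>= 0 up to the flooring).
#' @export
kl_divergence <- function(p_emp, q_model, eps = 1e-12) {
  if (length(p_emp) != length(q_model)) {
    rlang::abort("p_emp and q_model must have the same length",
      class = "sigburst_error_config")
  }
  stopifnot(abs(sum(p_emp) - 1) < 1e-8)
  q <- pmax(q_model, eps)
  nz <- p_emp > 0
  sum(p_emp[nz] * log(p_emp[nz] / q[nz]))
}

# censored model marginal for one FSP solution: columns are times; counts
# >= max_count (plus the sink mass) accumulate in the top bin
censored_model_marginal <- function(sol) {
  m <- marginal_matrix(sol)
  m[nrow(m), ] <- m[nrow(m), ] + sol$sink_mass
  m
}

# per-(gene, condition) FSP solves over the times present in the table
solve_for_table <- function(table, model, conds, fsp_args) {
  purrr::map(rlang::set_names(names(model$genes)), function(g) {
    purrr::map(rlang::set_names(conds), function(cond) {
      times <- sort(unique(table$time_s[table$condition == cond]))
      do.call(fsp_solve, c(list(gene = model$genes[[g]], condition = cond,
        sp = model$signal, times = times), fsp_args))
    })
  })
}

# precomputed empirical distributions for the optimizer's objective:
# emp[[gene]][[cond]] = list(times, P ((max_count+1) x T), n (cells per time))
empirical_cache <- function(table, genes, conds, max_count) {
  purrr::map(rlang::set_names(genes), function(g) {
    purrr::map(rlang::set_names(conds), function(cond) {
      times <- sort(unique(table$time_s[table$condition == cond]))
      ps <- purrr::map(times, function(tt)
        empirical_distribution(table, g, cond, tt, max_count))
      list(times = times,
           P = do.call(cbind, ps),
           n = purrr::map_dbl(ps, attr, "n_cells"))
    })
  })
}

# tibble-free objective used inside optimization loops
loglik_fast <- function(model, conds, emp, fsp_args) {
  total <- 0
  for (g in names(model$genes)) {
    for (cond in conds) {
      e <- emp[[g]][[cond]]
      sol <- do.call(fsp_solve, c(list(gene = model$genes[[g]],
        condition = cond, sp = model$signal, times = e$times), fsp_args))
      q <- marginal_matrix(sol)
      q[nrow(q), ] <- q[nrow(q), ] + sol$sink_mass
      lq <- log(pmax(q, 1e-12))[, match(e$times, sol$times), drop = FALSE]
      total <- total + sum(e$n * colSums(e$P * lq))
    }
  }
  total
}

dataset_terms <- function(table, model, conds, fsp_args) {
  sols <- solve_for_table(table, model, conds, fsp_args)
  purrr::map_dfr(names(model$genes), function(g) {
    purrr::map_dfr(conds, function(cond) {
      sol <- sols[[g]][[cond]]
      q <- censored_model_marginal(sol)
      times <- sort(unique(table$time_s[table$condition == cond]))
      purrr::map_dfr(times, function(tt) {
        j <- match(tt, sol$times)
        p <- empirical_distribution(table, g, cond, tt, sol$space$max_count)
        n <- attr(p, "n_cells")
        qq <- pmax(q[, j], 1e-12)
        nz <- p > 0
        tibble::tibble(gene = g, condition = cond, time_s = tt, n_cells = n,
          loglik = n * sum(p[nz] * log(qq[nz])),
          kl = kl_divergence(p, q[, j]))
      })
    })
  })
}

default_fsp_args <- function(fsp_args, table, model) {
  if (is.null(fsp_args$max_count)) {
    mx <- max(purrr::map_dbl(names(model$genes), function(g) {
      col <- paste0(g, "_count")
      if (col %in% names(table)) max(table[[col]]) else 0
    }))
    fsp_args$max_count <- max(64, 2 * ceiling(mx / 32) * 32)
  }
  fsp_args
}

#' Multinomial log-likelihood of a count table under a model
#'
#' Total log-likelihood (nats) of the per-gene marginal empirical
#' distributions: `sum` over genes, conditions and times of
#' `n_cells * sum_x phat(x) log q(x)`, where `q` is the FSP-predicted
#' marginal with counts above the truncation censored into the top bin on
#' both sides. Equals minus the cell-weighted sum of KL divergences up to
#' the data-only entropy constant. The FSP is solved once per (gene,
#' condition) over all times present.
#'
#' @param table Count table (see [generate_dataset()]).
#' @param model A [combinatorial_model()].
#' @param conds Conditions to include.
#' @param fsp_args List of extra arguments for [fsp_solve()] (`tol`,
#'   `max_count`, `rtol`, ...); `max_count` defaults to roughly twice the
#'   largest observed count.
#' @return Log-likelihood in nats (a scalar).
#' @export
dataset_loglik <- function(table, model, conds = training_conditions(),
                           fsp_args = list()) {
  assert_condition(conds)
  fsp_args <- default_fsp_args(fsp_args, table, model)
  sum(dataset_terms(table, model, conds, fsp_args)$loglik)
}

#' @describeIn dataset_loglik The cell-weighted sum of KL divergences
#'   (nats); `-dataset_kl` and `dataset_loglik` differ by the empirical
#'   entropy constant only.
#' @export
dataset_kl <- function(table, model, conds = training_conditions(),
                       fsp_args = list()) {
  assert_condition(conds)
  fsp_args <- default_fsp_args(fsp_args, table, model)
  terms <- dataset_terms(table, model, conds, fsp_args)
  sum(terms$n_cells * terms$kl)
}

# closed-form bound on the largest stationary mean any condition could
# reach (signal pinned at its peak): birth-death chain occupancy ratios,
# then mean = sum(alpha * pi) / delta. Used to reject absurd optimizer
# proposals before paying for an FSP solve.
predicted_mean_bound <- function(model, conds) {
  s_max <- nfkb_signal(signal_peak_time(model$signal), model$signal)
  max(purrr::map_dbl(model$genes, function(gene) {
    top <- gene$topology
    max(purrr::map_dbl(conds, function(cond) {
      r <- condition_rates(gene, cond)
      k <- r$k
      if (top$signal_mode == "enhance") {
        k[[top$signal_edge]] <- k[[top$signal_edge]] + r$b * s_max
      }  # suppression only lowers a down-rate; use the larger (basal) value
      pi_raw <- 1
      for (i in seq_len(top$n_states - 1)) {
        up <- paste0(i - 1, i); down <- paste0(i, i - 1)
        pi_raw <- c(pi_raw, pi_raw[i] * k[[up] ] /
          max(if (top$signal_mode == "suppress" && top$signal_edge == down)
            k[[down]] / (1 + r$b * s_max) else k[[down]], 1e-12))
      }
      pi <- pi_raw / sum(pi_raw)
      sum(r$alpha * pi) / r$delta
    }))
  }))
}

# largest total propensity any state of the truncated space can reach:
# explicit integration cost is proportional to it (stability-limited steps)
predicted_stiffness <- function(model, conds, max_count) {
  s_max <- nfkb_signal(signal_peak_time(model$signal), model$signal)
  max(purrr::map_dbl(model$genes, function(gene) {
    max(purrr::map_dbl(conds, function(cond) {
      r <- condition_rates(gene, cond)
      kmax <- if (length(r$k)) {
        k <- r$k
        if (gene$topology$signal_mode == "enhance") {
          k[[gene$topology$signal_edge]] <-
            k[[gene$topology$signal_edge]] + r$b * s_max
        }
        max(k)
      } else 0
      kmax + max(r$alpha) + r$delta * (max_count + 1)
    }))
  }))
}

# ---- parameter vector <-> model -------------------------------------------

free_param_names <- function(model, conds) {
  nm <- c("r1", "r2")
  for (g in names(model$genes)) {
    gene <- model$genes[[g]]
    nm <- c(nm, paste0(g, ".k", gene$topology$edges),
      if (gene$topology$signal_mode != "none") paste0(g, ".b"),
      paste0(g, ".alpha", seq_len(gene$topology$n_states) - 1),
      paste0(g, ".delta"))
    if (any(c("mg132", "both") %in% conds)) nm <- c(nm, paste0(g, ".b_mg132"))
    if (any(c("u0126", "both") %in% conds)) nm <- c(nm, paste0(g, ".k01_u0126"))
  }
  nm
}

get_model_params <- function(model, conds) {
  out <- c(r1 = model$signal$r1, r2 = model$signal$r2)
  for (g in names(model$genes)) {
    gene <- model$genes[[g]]
    k <- gene$rates$k
    names(k) <- paste0(g, ".k", gene$topology$edges)
    a <- gene$rates$alpha
    names(a) <- paste0(g, ".alpha", seq_along(a) - 1)
    out <- c(out, k,
      if (gene$topology$signal_mode != "none")
        rlang::set_names(gene$rates$b, paste0(g, ".b")),
      a, rlang::set_names(gene$rates$delta, paste0(g, ".delta")))
    if (any(c("mg132", "both") %in% conds)) {
      out <- c(out, rlang::set_names(
        if (is.null(gene$inhibitors)) gene$rates$b else gene$inhibitors$mg132$b,
        paste0(g, ".b_mg132")))
    }
    if (any(c("u0126", "both") %in% conds)) {
      out <- c(out, rlang::set_names(
        if (is.null(gene$inhibitors)) gene$rates$k[["01"]] else
          gene$inhibitors$u0126$k01,
        paste0(g, ".k01_u0126")))
    }
  }
  out
}

set_model_params <- function(model, params) {
  if ("r1" %in% names(params)) model$signal$r1 <- unname(params[["r1"]])
  if ("r2" %in% names(params)) model$signal$r2 <- unname(params[["r2"]])
  for (g in names(model$genes)) {
    gene <- model$genes[[g]]
    for (e in gene$topology$edges) {
      nm <- paste0(g, ".k", e)
      if (nm %in% names(params)) gene$rates$k[[e]] <- unname(params[[nm]])
    }
    nm <- paste0(g, ".b")
    if (nm %in% names(params)) gene$rates$b <- unname(params[[nm]])
    for (i in seq_along(gene$rates$alpha)) {
      nm <- paste0(g, ".alpha", i - 1)
      if (nm %in% names(params)) gene$rates$alpha[i] <- unname(params[[nm]])
    }
    nm <- paste0(g, ".delta")
    if (nm %in% names(params)) gene$rates$delta <- unname(params[[nm]])
    pget <- function(nm) {
      if (nm %in% names(params)) unname(params[[nm]]) else NULL
    }
    bmg <- pget(paste0(g, ".b_mg132")) %||%
      (if (!is.null(gene$inhibitors)) gene$inhibitors$mg132$b)
    ku <- pget(paste0(g, ".k01_u0126")) %||%
      (if (!is.null(gene$inhibitors)) gene$inhibitors$u0126$k01)
    if (!is.null(bmg) || !is.null(ku)) {
      gene$inhibitors <- inhibitor_map(
        b_mg132 = bmg %||% gene$rates$b,
        k01_u0126 = ku %||% gene$rates$k[["01"]])
    }
    model$genes[[g]] <- gene
  }
  model
}

#' Optimizer configuration for model fitting
#'
#' @param n_starts Number of multistart repetitions; the first start is the
#'   template's own parameter values, the rest are log-uniform draws within
#'   the bounds.
#' @param method `"neldermead"` or `"lbfgsb"` local search in log10
#'   parameter space.
#' @param maxit Iteration budget per start.
#' @param lower,upper Parameter bounds (natural scale), applied to every
#'   free parameter.
#' @param seed Integer seed for the random starts (mandatory).
#' @param fixed Character vector of parameter names held at their template
#'   values (e.g. `c("r1", "r2")`).
#' @param fsp_args Extra arguments for [fsp_solve()] during objective
#'   evaluation.
#' @return A list of class `sigburst_opt_config`.
#' @export
opt_config <- function(n_starts = 20, method = c("neldermead", "lbfgsb"),
                       maxit = 500, lower = 1e-7, upper = 1e1, seed = NULL,
                       fixed = character(), fsp_args = list(tol = 1e-4),
                       stiff_cap = 4) {
  method <- match.arg(method)
  if (is.null(seed)) {
    rlang::abort("opt_config requires an explicit seed",
      class = "sigburst_error_config")
  }
  structure(list(n_starts = n_starts, method = method, maxit = maxit,
    lower = lower, upper = upper, seed = as.integer(seed), fixed = fixed,
    fsp_args = fsp_args, stiff_cap = stiff_cap),
    class = "sigburst_opt_config")
}

#' Fit a combinatorial model to a count table
#'
#' Maximizes [dataset_loglik()] (equivalently, minimizes the cell-weighted
#' sum of KL divergences) over the log10-transformed free parameters: the
#' shared signal rates `r1`, `r2`, every gene's switching rates, signal
#' coefficient, transcription rates and degradation rate, and the inhibitor
#' substitution values required by the training conditions. Multistart local
#' optimization; deterministic given `opt$seed`. The held-out combined-drug
#' condition is refused as training data.
#'
#' @param model_template A [combinatorial_model()] providing topologies and
#'   starting values.
#' @param table Count table containing all `conds`.
#' @param conds Training conditions (must not include `"both"`).
#' @param opt An [opt_config()].
#' @return A `sigburst_fit` object: the fitted `model`, `loglik`,
#'   `n_params`, `n_obs`, and a `trace` tibble with every start's endpoint.
#' @export
fit_model <- function(model_template, table, conds = training_conditions(),
                      opt = opt_config(seed = 1)) {
  stopifnot(inherits(model_template, "sigburst_model"),
    inherits(opt, "sigburst_opt_config"))
  assert_condition(conds)
  if ("both" %in% conds) {
    rlang::abort(paste("the combined-inhibitor condition is held out for",
      "testing and cannot be used for training"),
      class = "sigburst_error_training")
  }
  missing_conds <- setdiff(conds, unique(table$condition))
  if (length(missing_conds) > 0) {
    rlang::abort(paste0("table lacks training condition(s): ",
      paste(missing_conds, collapse = ", ")),
      class = "sigburst_error_config")
  }
  fsp_args <- default_fsp_args(opt$fsp_args, table, model_template)
  # during optimization the truncation is held fixed and the tail handled by
  # consistent top-bin censoring, so arbitrary parameter proposals cannot
  # trigger unbounded state-space expansion
  if (is.null(fsp_args$expand)) fsp_args$expand <- FALSE

  nm_all <- free_param_names(model_template, conds)
  nm_free <- setdiff(nm_all, opt$fixed)
  theta0 <- get_model_params(model_template, conds)
  lb <- log10(opt$lower); ub <- log10(opt$upper)

  # proposals whose stationary mean dwarfs the censored space are rejected
  # with a graded penalty before any solve: their dynamics live entirely in
  # the top censoring bin, and integrating them is stability-limited (slow)
  mean_cap <- 20 * (fsp_args$max_count + 1)
  stiff_cap <- opt$stiff_cap %||% 4  # per second; cost guard, see opt_config
  emp <- empirical_cache(table, names(model_template$genes), conds,
    fsp_args$max_count)
  neg_loglik <- function(ltheta) {
    params <- rlang::set_names(10^ltheta, nm_free)
    m <- set_model_params(model_template, params)
    mb <- predicted_mean_bound(m, conds)
    if (mb > mean_cap) return(1e9 * (1 + log10(mb / mean_cap)))
    st <- predicted_stiffness(m, conds, fsp_args$max_count)
    if (st > stiff_cap) return(1e9 * (1 + log10(st / stiff_cap)))
    val <- tryCatch(
      -loglik_fast(m, conds, emp, fsp_args),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  old <- set_local_seed(opt$seed)
  on.exit(restore_seed(old))
  starts <- purrr::map(seq_len(opt$n_starts), function(i) {
    if (i == 1) {
      pmin(pmax(log10(theta0[nm_free]), lb), ub)
    } else {
      rlang::set_names(stats::runif(length(nm_free), lb, ub), nm_free)
    }
  })

  runs <- purrr::imap(starts, function(s0, i) {
    res <- if (opt$method == "lbfgsb") {
      stats::optim(s0, neg_loglik, method = "L-BFGS-B", lower = lb, upper = ub,
        control = list(maxit = opt$maxit, factr = 1e9))
    } else {
      r <- stats::optim(s0, neg_loglik, method = "Nelder-Mead",
        control = list(maxit = opt$maxit))
      r$par <- pmin(pmax(r$par, lb), ub)
      r
    }
    list(start = i, par = res$par, value = res$value,
      convergence = res$convergence, counts = res$counts[["function"]])
  })

  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  params <- rlang::set_names(10^best$par, nm_free)
  fitted_model <- set_model_params(model_template, params)
  terms <- dataset_terms(table, fitted_model, conds, fsp_args)
  trace <- purrr::map_dfr(runs, function(r) {
    tibble::tibble(start = r$start, neg_loglik = r$value,
      convergence = r$convergence, n_evals = r$counts)
  })
  structure(list(
    model = fitted_model, loglik = -best$value, n_params = length(nm_free),
    n_obs = sum(terms$n_cells), conds = conds, trace = trace,
    opt = opt[c("n_starts", "method", "maxit", "seed")],
    fsp_args = fsp_args, terms = terms),
    class = "sigburst_fit")
}

#' @export
print.sigburst_fit <- function(x, ...) {
  cat(sprintf("<sigburst_fit> %s: loglik %.1f, %d free parameters, %d cells\n",
    x$model$name, x$loglik, x$n_params, x$n_obs))
  invisible(x)
}

#' Serialize a fit as JSON
#'
#' Parameter names match the standard rate symbols (`k01`, `b01`, ...,
#' `k01_U0126`), with the MG132/U0126 substitutions included, plus `loglik`,
#' `n_params`, `n_obs` and optimizer metadata.
#'
#' @param fit A `sigburst_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sigburst_fit"))
  params <- as.list(get_model_params(fit$model, fit$conds))
  jsonlite::write_json(list(
    model = fit$model$name, parameters = params, loglik = fit$loglik,
    n_params = fit$n_params, n_obs = fit$n_obs,
    optimizer = fit$opt, conditions = fit$conds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.sigburst_fit <- function(x, ...) {
  p <- get_model_params(x$model, x$conds)
  tibble::tibble(term = names(p), estimate = unname(p))
}

#' @exportS3Method generics::glance
glance.sigburst_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_params = x$n_params, n_obs = x$n_obs,
    BIC = bic(x$loglik, x$n_params, x$n_obs))
}
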