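# Global survival fitting: simultaneous, replicate-weighted least squares of
# ln(SF) across all cell lines and doses for a chosen RBE model, under the
# ordering constraints R0 >= 1 and (dual model) R0 <= R1 <= R2 enforced at
# the smallest alpha_x/beta_x among the fitted cell lines. The global search
# is a differential-evolution optimiser followed by a local polish; model
# performance is benchmarked by the RMSE of predicted vs measured ln(SF).

FIT_MODEL_KINDS <- c("dd3", "dd7", "dd10", "dd3_7", "dd3_10", "letd", "qeffd")

fit_kind_to_params <- function(model_kind, theta, ab_min) {
  switch(model_kind,
    dd3 = , dd7 = , dd10 = {
      thr <- as.numeric(sub("dd", "", model_kind))
      model_params("ddk_single", r0 = theta[1],
                   rhat_d = theta[1] * ab_min + theta[2], thresholds = thr)
    },
    dd3_7 = , dd3_10 = {
      thr <- as.numeric(strsplit(sub("dd", "", model_kind), "_")[[1]])
      r1 <- theta[1] * ab_min + theta[2]
      model_params("ddk_dual", r0 = theta[1], rhat_1 = r1,
                   rhat_2 = r1 + theta[3], thresholds = thr)
    },
    letd = model_params("letd_linear", r0 = theta[1], t = theta[2]),
    qeffd = model_params("qeffd_linear", r0 = theta[1], t = theta[2]),
    stop("unknown model kind: ", model_kind, call. = FALSE)
  )
}

fit_bounds <- function(model_kind, ab_min) {
  r0 <- c(1, 3)
  switch(model_kind,
    dd3 = , dd7 = , dd10 = list(lower = c(r0[1], 0), upper = c(r0[2], 100)),
    dd3_7 = , dd3_10 = list(lower = c(r0[1], 0, 0), upper = c(r0[2], 100, 100)),
    letd = list(lower = c(r0[1], 0), upper = c(r0[2], 10)),
    qeffd = list(lower = c(r0[1], 0), upper = c(r0[2], 2))
  )
}

validate_records <- function(records, model_kind) {
  need <- c("cell_line", "alpha_x", "beta_x", "dose", "sf", "replicates")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("no survival records to fit", call. = FALSE)
  bad <- which(!is.finite(records$sf) | records$sf <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite SF in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  metric_cols <- switch(model_kind,
    dd3 = "f_3", dd7 = "f_7", dd10 = "f_10",
    dd3_7 = c("f_3", "f_7"), dd3_10 = c("f_3", "f_10"),
    letd = "letd", qeffd = "qeffd")
  miss <- setdiff(metric_cols, names(records))
  if (length(miss)) {
    stop("records lack the quality metric column(s) ",
         paste(miss, collapse = ", "),
         "; run attach_quality_metrics() first", call. = FALSE)
  }
  records
}

# weighted SSE of ln SF as a function of the transformed parameter vector
make_objective <- function(records, model_kind, ab_min) {
  records$abr <- records$alpha_x / records$beta_x
  lnsf <- log(records$sf)
  w <- records$replicates / sum(records$replicates)
  d <- records$dose
  quad <- records$beta_x * d^2
  function(theta) {
    params <- fit_kind_to_params(model_kind, theta, ab_min)
    alpha <- predict_alpha(params, records, records)
    resid <- lnsf - (-alpha * d - quad)
    sum(w * resid^2)
  }
}

# compact differential evolution (rand/1/bin) with box bounds
de_optimize <- function(fn, lower, upper, seed, np = NULL, iters = 200L,
                        f = 0.8, cr = 0.9) {
  set.seed(seed)
  p <- length(lower)
  np <- np %||% max(10L * p, 20L)
  pop <- matrix(stats::runif(np * p, lower, upper), np, p, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (it in seq_len(iters)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3L)
      mutant <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(p) < cr
      cross[sample.int(p, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

#' Global fit of an RBE model to survival records
#'
#' Minimises the replicate-weighted sum of squared ln(SF) residuals over all
#' cell lines and doses simultaneously, for one model family. The search is
#' global (differential evolution, seeded) followed by an `nlminb` polish;
#' a deterministic multi-start local mode is available. Constraints: `R0 >=
#' 1` for all models, and for dual-threshold models the ordering `1 <= R0 <=
#' R1 <= R2`, enforced at the smallest `alpha_x/beta_x` among the fitted
#' cell lines (the binding case). Parameters are reported together with any
#' active constraint boundaries.
#'
#' @param records survival records with quality metrics attached (see
#'   [attach_quality_metrics()] or [generate_jig_dataset()]): columns
#'   `cell_line`, `alpha_x`, `beta_x`, `dose` (Gy), `sf`, `replicates`, and
#'   the model's metric column(s) (`f_<thr>`, `letd`, `qeffd`).
#' @param model_kind one of `"dd3"`, `"dd7"`, `"dd10"` (single-threshold
#'   dirty dose), `"dd3_7"`, `"dd3_10"` (dual), `"letd"`, `"qeffd"`.
#' @param seed integer seed for the stochastic optimiser.
#' @param method `"de"` (differential evolution + polish, default) or
#'   `"multistart"` (deterministic local fits from fixed starts).
#' @param de_iters,de_np differential-evolution generations / population.
#' @return A `ddk_fit` object; see [tidy.ddk_fit()] and [glance.ddk_fit()].
#' @examples
#' \donttest{
#' rec <- generate_jig_dataset(jig_config(seed = 1))
#' fit <- fit_global(rec, "dd7", seed = 1)
#' glance(fit)
#' }
#' @export
fit_global <- function(records, model_kind = FIT_MODEL_KINDS, seed = 1L,
                       method = c("de", "multistart"),
                       de_iters = 150L, de_np = NULL) {
  model_kind <- match.arg(model_kind)
  method <- match.arg(method)
  records <- validate_records(records, model_kind)
  if ("quality_ok" %in% names(records)) {
    records <- records[records$quality_ok, , drop = FALSE]
  }
  ab_min <- min(records$alpha_x / records$beta_x)
  fn <- make_objective(records, model_kind, ab_min)
  b <- fit_bounds(model_kind, ab_min)
  if (method == "de") {
    glob <- de_optimize(fn, b$lower, b$upper, seed = seed,
                        iters = de_iters, np = de_np)
    start <- glob$par
  } else {
    p <- length(b$lower)
    starts <- rbind(b$lower + 0.1 * (b$upper - b$lower),
                    (b$lower + b$upper) / 2,
                    b$lower + c(0, rep(0.02, p - 1)))
    vals <- apply(starts, 1, fn)
    start <- starts[which.min(vals), ]
  }
  pol <- stats::nlminb(start, fn, lower = b$lower, upper = b$upper,
                       control = list(rel.tol = 1e-14, abs.tol = 0))
  theta <- pol$par
  params <- fit_kind_to_params(model_kind, theta, ab_min)
  tol <- 1e-5
  active <- character(0)
  if (theta[1] - b$lower[1] < tol) active <- c(active, "r0")
  if (length(theta) >= 2 && theta[2] - b$lower[2] < tol) {
    active <- c(active, switch(params$kind, ddk_single = "rhat_d",
                               ddk_dual = "rhat_1", "t"))
  }
  if (length(theta) >= 3 && theta[3] - b$lower[3] < tol) {
    active <- c(active, "rhat_2")
  }
  fit <- structure(list(
    params = params, model_kind = model_kind, theta = theta,
    ab_min = ab_min, n_points = nrow(records), seed = as.integer(seed),
    method = method, objective = pol$objective,
    active_bounds = active, records = tibble::as_tibble(records)
  ), class = "ddk_fit")
  fit$rmse_weighted <- fit_rmse(fit, weighted = TRUE)
  fit$rmse_unweighted <- fit_rmse(fit, weighted = FALSE)
  fit
}

#' Predicted ln(SF) for survival records
#'
#' @param object a `ddk_fit`.
#' @param newdata records to predict (default: the fitted records).
#' @param ... unused.
#' @return Numeric vector of predicted natural-log surviving fractions.
#' @export
predict.ddk_fit <- function(object, newdata = NULL, ...) {
  records <- newdata %||% object$records
  records$abr <- records$alpha_x / records$beta_x
  alpha <- predict_alpha(object$params, records, records)
  -alpha * records$dose - records$beta_x * records$dose^2
}

#' RMSE of a fitted model on ln(SF)
#'
#' Root-mean-square error of predicted vs measured natural-log surviving
#' fraction. The replicate-weighted form is consistent with the fitting
#' objective; the unweighted form treats every record equally.
#'
#' @param fit a `ddk_fit`.
#' @param records records to evaluate (default: the fitted ones).
#' @param weighted replicate-weighted (default) or unweighted.
#' @return RMSE (dimensionless, on ln SF).
#' @export
fit_rmse <- function(fit, records = NULL, weighted = TRUE) {
  records <- records %||% fit$records
  resid <- log(records$sf) - predict(fit, records)
  w <- if (weighted) records$replicates else rep(1, nrow(records))
  sqrt(sum(w * resid^2) / sum(w))
}

#' @export
print.ddk_fit <- function(x, ...) {
  cat(sprintf("<ddk_fit: %s, n = %d, RMSE(lnSF) = %.4f (weighted)>\n",
              x$model_kind, x$n_points, x$rmse_weighted))
  print(x$params)
  if (length(x$active_bounds)) {
    cat("  parameters at constraint boundary:",
        paste(x$active_bounds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fitted model parameters
#'
#' @param x a `ddk_fit`.
#' @param ... unused.
#' @return Tibble with one row per fitted parameter: `term`, `estimate`,
#'   `at_bound`.
#' @exportS3Method generics::tidy
tidy.ddk_fit <- function(x, ...) {
  p <- x$params
  terms <- switch(p$kind,
    ddk_single = c(r0 = p$r0, rhat_d = p$rhat_d),
    ddk_dual = c(r0 = p$r0, rhat_1 = p$rhat_1, rhat_2 = p$rhat_2),
    c(r0 = p$r0, t = p$t))
  tibble::tibble(term = names(terms), estimate = unname(terms),
                 at_bound = names(terms) %in% x$active_bounds)
}

#' One-row fit summary
#'
#' @inheritParams tidy.ddk_fit
#' @return Tibble: `model`, `n`, `rmse_weighted`, `rmse_unweighted`,
#'   `objective`, `seed`.
#' @exportS3Method generics::glance
glance.ddk_fit <- function(x, ...) {
  tibble::tibble(model = x$model_kind, n = x$n_points,
                 rmse_weighted = x$rmse_weighted,
                 rmse_unweighted = x$rmse_unweighted,
                 objective = x$objective, seed = x$seed)
}

#' Benchmark several RBE models on the same records
#'
#' Runs [fit_global()] per model on identical records and returns the fits
#' ranked by weighted RMSE. Deterministic for a given seed.
#'
#' @inheritParams fit_global
#' @param model_kinds character vector of model kinds to compare.
#' @return Tibble ranked by `rmse_weighted`, with the fit objects in a
#'   `fit` list-column; class `ddk_benchmark`.
#' @export
benchmark_models <- function(records, model_kinds = FIT_MODEL_KINDS,
                             seed = 1L, method = "de", de_iters = 150L) {
  fits <- lapply(model_kinds, function(k) {
    fit_global(records, k, seed = seed, method = method, de_iters = de_iters)
  })
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$fit <- fits
  out <- dplyr::arrange(out, .data$rmse_weighted)
  class(out) <- c("ddk_benchmark", class(out))
  out
}
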