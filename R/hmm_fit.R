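#' Fit Dnmt efficiencies by joint maximum likelihood over knockout regimes
#'
#' Maximizes the joint multinomial [log_likelihood()] of dyad-class counts
#' across cell-line regimes over the box-constrained efficiency parameters
#' (`mu_e`, `delta_e` for every enzyme active in at least one regime).
#' Knockout lines provide the informative contrasts; the parental wild type
#' usually enters only through the initial distributions `pi0` and as
#' held-out validation via [predict_wt()] (add it as a regime to include it
#' in the likelihood). Optimisation is bounded quasi-Newton (`L-BFGS-B`)
#' from `n_starts` Latin-hypercube starting points drawn under a fixed seed;
#' the best optimum is reported, with ties broken towards the smallest
#' parameter L2 norm. Optionally the generation count of every regime is
#' replaced by `g = generations_scale * regime$generations` with the single
#' shared scale fitted in `gen_scale_bounds` (for designs where only
#' passage numbers are known).
#'
#' @param count_tables List of `dyad_count_table`s (or named analyzable
#'   count vectors), parallel to `regimes`.
#' @param regimes List of [cell_line_regime()]s with distinct active-enzyme
#'   sets (at least 2).
#' @param mode `"free"` or `"tied"` (see [dnmt_params()]).
#' @param c_fail,c_over Conversion error rates, fixed (not fitted);
#'   `c_fail` should be the sample's measured linker conversion-failure
#'   rate.
#' @param n_starts Number of multi-starts (default 10).
#' @param start_seed Seed for the Latin-hypercube starts (default 17).
#' @param fit_generations If `TRUE`, fit a shared generation-count scale.
#' @param gen_scale_bounds Bounds for that scale (default `c(0.25, 4)`).
#' @param sd_flag_threshold Standard deviations above this flag a parameter
#'   as non-identifiable (default 0.15).
#' @return Object of class `dnmt_fit`: `estimates` (named vector over the
#'   free parameters), `sd`, `flags` (logical, `TRUE` = non-identifiable),
#'   `loglik`, `convergence` (`"converged"` or `"not_converged"`),
#'   `params` (a [dnmt_params()] at the optimum), `predicted` (per-regime
#'   predicted vs observed class proportions), plus the inputs needed to
#'   recompute the Hessian.
#' @export
fit_dnmt <- function(count_tables, regimes, mode = c("free", "tied"),
                     c_fail = 0, c_over = 0, n_starts = 10L,
                     start_seed = 17L, fit_generations = FALSE,
                     gen_scale_bounds = c(0.25, 4),
                     sd_flag_threshold = 0.15) {
  mode <- match.arg(mode)
  stopifnot(length(regimes) >= 2L, length(count_tables) == length(regimes))
  active_union <- unique(unlist(lapply(regimes, `[[`, "active_enzymes")))
  free_enz <- intersect(DNMT_ENZYMES, active_union)
  if (!length(free_enz)) stop("no enzyme active in any regime", call. = FALSE)

  par_names <- c(paste0("mu_", free_enz), paste0("delta_", free_enz))
  lower <- rep(0, length(par_names))
  upper <- rep(1, length(par_names))
  if (fit_generations) {
    par_names <- c(par_names, "gen_scale")
    lower <- c(lower, gen_scale_bounds[1])
    upper <- c(upper, gen_scale_bounds[2])
  }
  k <- length(par_names)

  build <- function(theta) {
    names(theta) <- par_names
    mu <- stats::setNames(numeric(3), DNMT_ENZYMES)
    delta <- mu
    mu[free_enz] <- theta[paste0("mu_", free_enz)]
    delta[free_enz] <- theta[paste0("delta_", free_enz)]
    p <- dnmt_params(mu, delta, mode = mode, c_fail = c_fail,
                     c_over = c_over)
    rg <- regimes
    if (fit_generations) {
      for (i in seq_along(rg))
        rg[[i]]$generations <- theta[["gen_scale"]] * rg[[i]]$generations
    }
    list(params = p, regimes = rg)
  }
  nll <- function(theta) {
    b <- build(theta)
    -log_likelihood(b$params, b$regimes, count_tables)
  }

  starts <- .with_seed(start_seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) ||
        res$value < best$value - 1e-9 ||
        (abs(res$value - best$value) <= 1e-9 &&
         sum(res$par^2) < sum(best$par^2))) {
      best <- res
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  theta <- stats::setNames(best$par, par_names)
  b <- build(theta)
  sds <- .fit_sds(nll, theta, lower, upper)
  flags <- sds$sd > sd_flag_threshold | sds$singular |
    theta <= lower + 1e-6 | theta >= upper - 1e-6
  never_active <- setdiff(DNMT_ENZYMES, free_enz)

  predicted <- lapply(seq_along(regimes), function(i) {
    rg <- b$regimes[[i]]
    q <- state_distribution(rg$pi0, b$params, rg$active_enzymes,
                            rg$generations) %*% emission_matrix(b$params)
    obs <- .analyzable(count_tables[[i]])
    data.frame(class = analyzable_classes(),
               predicted = as.numeric(q),
               observed = as.numeric(obs / sum(obs)))
  })
  names(predicted) <- vapply(regimes, `[[`, "", "line_name")

  structure(list(
    estimates = theta, sd = sds$sd, flags = flags,
    loglik = -best$value,
    convergence = if (n_conv > 0L) "converged" else "not_converged",
    n_converged_starts = n_conv, n_starts = n_starts,
    hessian_singular = sds$singular_any,
    params = b$params, mode = mode, c_fail = c_fail, c_over = c_over,
    free_enzymes = free_enz, never_active = never_active,
    fit_generations = fit_generations,
    regimes = regimes, count_tables = count_tables,
    predicted = predicted
  ), class = "dnmt_fit")
}

# SDs from the inverse observed Fisher information: numerical Hessian of the
# negative log-likelihood (central differences, step 1e-4, evaluation points
# projected into the interior of the box); singular curvature falls back to
# the Moore-Penrose pseudo-inverse and is flagged.
.fit_sds <- function(nll, theta, lower, upper, h = 1e-4) {
  k <- length(theta)
  th <- pmin(pmax(theta, lower + 2 * h), upper - 2 * h)
  H <- matrix(NA_real_, k, k)
  f0 <- nll(th)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (nll(th + ei) - 2 * f0 + nll(th - ei)) / h^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (nll(th + ei + ej) - nll(th + ei - ej) -
         nll(th - ei + ej) + nll(th - ei - ej)) / (4 * h^2)
    }
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  singular_any <- is.null(cov) || any(diag(cov) <= 0)
  if (is.null(cov)) cov <- MASS::ginv(H)
  v <- diag(cov)
  sd <- sqrt(pmax(v, 0))
  sd[v <= 0] <- Inf
  list(sd = stats::setNames(sd, names(theta)),
       singular = !is.finite(sd) | v <= 0,
       singular_any = singular_any)
}

#' Standard deviations of fitted efficiencies
#'
#' Recomputes the approximate standard deviations of a converged
#' [fit_dnmt()] from the inverse observed Fisher information (numerical
#' Hessian of the negative log-likelihood at the estimate).
#'
#' @param fit A `dnmt_fit`.
#' @param count_tables Count tables (defaults to those stored in the fit).
#' @return Named vector of standard deviations with attribute `flags`.
#' @export
standard_deviations <- function(fit, count_tables = fit$count_tables) {
  stopifnot(inherits(fit, "dnmt_fit"))
  regimes <- fit$regimes
  free_enz <- fit$free_enzymes
  theta <- fit$estimates
  nll <- function(th) {
    names(th) <- names(theta)
    mu <- stats::setNames(numeric(3), DNMT_ENZYMES)
    delta <- mu
    mu[free_enz] <- th[paste0("mu_", free_enz)]
    delta[free_enz] <- th[paste0("delta_", free_enz)]
    p <- dnmt_params(mu, delta, mode = fit$mode, c_fail = fit$c_fail,
                     c_over = fit$c_over)
    rg <- regimes
    if (fit$fit_generations) {
      for (i in seq_along(rg))
        rg[[i]]$generations <- th[["gen_scale"]] * rg[[i]]$generations
    }
    -log_likelihood(p, rg, count_tables)
  }
  k <- length(theta)
  sds <- .fit_sds(nll, theta, rep(0, k), rep(1, k))
  structure(sds$sd, flags = sds$singular | sds$sd > 0.15)
}

#' Predict wild-type dyad-class proportions from fitted efficiencies
#'
#' Runs the fitted chain with all three enzymes active — by default to its
#' stationary distribution (tolerance 1e-10), or for `g_wt` generations
#' from `pi0` — maps it through the emission matrix, aggregates the two
#' hemimethylated classes, and reports the maximum absolute difference to
#' the observed wild-type proportions over the three categories
#' unmethylated / hemimethylated / fully methylated.
#'
#' @param fit A converged `dnmt_fit`.
#' @param wt_counts Observed wild-type `dyad_count_table` (or named vector).
#' @param g_wt Optional finite generation count; default is stationarity.
#' @param pi0 Start distribution when `g_wt` is finite.
#' @return List with `predicted`, `observed` (named proportions over
#'   `unmeth`, `hemi`, `full`) and `max_error`.
#' @export
predict_wt <- function(fit, wt_counts, g_wt = NULL,
                       pi0 = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(inherits(fit, "dnmt_fit"))
  pi_wt <- if (is.null(g_wt)) {
    stationary_distribution(fit$params, DNMT_ENZYMES, pi0 = pi0)
  } else {
    state_distribution(pi0, fit$params, DNMT_ENZYMES, g_wt)
  }
  q <- as.numeric(pi_wt %*% emission_matrix(fit$params))
  pred <- c(unmeth = q[1], hemi = q[2] + q[3], full = q[4])
  obs_counts <- .analyzable(wt_counts)
  op <- obs_counts / sum(obs_counts)
  obs <- c(unmeth = unname(op[["UNMETH"]]),
           hemi = unname(op[["HEMI_UPPER"]] + op[["HEMI_LOWER"]]),
           full = unname(op[["FULL"]]))
  list(predicted = pred, observed = obs,
       max_error = max(abs(pred - obs)))
}

#' @export
print.dnmt_fit <- function(x, ...) {
  cat(sprintf("dnmt_fit (%s mode): loglik %.2f, %s (%d/%d starts)\n",
              x$mode, x$loglik, x$convergence, x$n_converged_starts,
              x$n_starts))
  df <- data.frame(estimate = round(x$estimates, 4),
                   sd = round(x$sd, 4),
                   flag = ifelse(x$flags, "non_identifiable", ""))
  print(df)
  if (length(x$never_active))
    cat("never active (fixed 0):", paste(x$never_active, collapse = ", "),
        "\n")
  invisible(x)
}
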