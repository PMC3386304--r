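#' Methyltransferase efficiency parameters
#'
#' Per enzyme (Dnmt1, Dnmt3a, Dnmt3b): `mu` is the probability per
#' replication of methylating the unmethylated cytosine of a hemimethylated
#' dyad (maintenance-type activity); `delta` the probability of methylating
#' a cytosine of a fully unmethylated dyad (de novo activity). In `"free"`
#' mode the two act separately; in `"tied"` mode de novo activity also acts
#' on hemimethylated dyads on top of maintenance (the parameterization in
#' which de novo methylation is equally likely at unmethylated and
#' hemimethylated positions). `c_fail` is the probability that an
#' unmethylated C escapes bisulfite conversion and reads as methylated;
#' `c_over` the probability that a methylated C reads as converted.
#'
#' @param mu,delta Named numeric vectors over `Dnmt1`, `Dnmt3a`, `Dnmt3b`
#'   (missing enzymes default to 0; knocked-out enzymes must be exactly 0).
#' @param mode `"free"` or `"tied"`.
#' @param c_fail,c_over Conversion error probabilities.
#' @return Object of class `dnmt_params`.
#' @examples
#' dnmt_params(mu = c(Dnmt1 = 0.95), delta = c(Dnmt1 = 0.3))
#' @export
dnmt_params <- function(mu = c(Dnmt1 = 0, Dnmt3a = 0, Dnmt3b = 0),
                        delta = c(Dnmt1 = 0, Dnmt3a = 0, Dnmt3b = 0),
                        mode = c("free", "tied"),
                        c_fail = 0, c_over = 0) {
  mode <- match.arg(mode)
  full <- function(x) {
    out <- stats::setNames(numeric(3), DNMT_ENZYMES)
    if (length(x)) {
      if (is.null(names(x)) && length(x) == 3L) names(x) <- DNMT_ENZYMES
      bad <- setdiff(names(x), DNMT_ENZYMES)
      if (length(bad)) stop("unknown enzyme: ", bad[1], call. = FALSE)
      out[names(x)] <- x
    }
    out
  }
  mu <- full(mu); delta <- full(delta)
  .check_prob(c(mu, delta, c_fail, c_over), "efficiencies and error rates")
  structure(list(mu = mu, delta = delta, mode = mode,
                 c_fail = c_fail, c_over = c_over),
            class = "dnmt_params")
}

#' Cell-line regime: active enzymes, generations, initial distribution
#'
#' @param line_name Identifier.
#' @param active_enzymes Character subset of `Dnmt1`, `Dnmt3a`, `Dnmt3b`
#'   (knockouts are the complement).
#' @param generations Number of cell generations since derivation (the
#'   transient phase length); must be >= 1.
#' @param pi0 Initial distribution over the dyad states `U, HU, HL, M`
#'   (typically the observed parental wild-type class proportions).
#' @param passage Optional passage number (bookkeeping only).
#' @return Object of class `cell_line_regime`.
#' @export
cell_line_regime <- function(line_name, active_enzymes, generations, pi0,
                             passage = NULL) {
  stopifnot(all(active_enzymes %in% DNMT_ENZYMES), generations >= 1)
  pi0 <- as.numeric(pi0)
  if (length(pi0) != 4L || abs(sum(pi0) - 1) > 1e-12 || any(pi0 < 0))
    stop("pi0 must be a length-4 distribution summing to 1 (tol 1e-12)",
         call. = FALSE)
  names(pi0) <- dyad_states()
  structure(list(line_name = line_name,
                 active_enzymes = unique(active_enzymes),
                 generations = as.numeric(generations),
                 pi0 = pi0, passage = passage),
            class = "cell_line_regime")
}

#' One-generation dyad-state transition matrix
#'
#' One cell generation is semi-conservative replication followed by a single
#' simultaneous enzymatic pass. Replication segregates strands: a fully
#' methylated dyad becomes hemimethylated on the inherited strand (upper or
#' lower with probability 1/2 each), a hemimethylated dyad keeps its
#' methylated strand with probability 1/2 and otherwise becomes
#' unmethylated, an unmethylated dyad stays unmethylated. The enzymatic pass
#' combines the active enzymes independently: maintenance
#' `h* = 1 - prod(1 - mu_e)` fills the unmethylated cytosine of a
#' hemimethylated dyad (in `"tied"` mode with probability
#' `1 - (1 - h*)(1 - d*)`), and de novo `d* = 1 - prod(1 - delta_e)` acts on
#' each cytosine of an unmethylated dyad independently (so `U -> M` in one
#' generation has probability `d*^2`). A cytosine methylated in this pass
#' cannot trigger maintenance of its partner within the same pass.
#'
#' @param params A [dnmt_params()] object.
#' @param active_enzymes Character vector of enzymes present in the line.
#' @return 4x4 row-stochastic matrix over states `U, HU, HL, M`.
#' @export
replication_transition <- function(params, active_enzymes = DNMT_ENZYMES) {
  stopifnot(inherits(params, "dnmt_params"))
  active <- intersect(DNMT_ENZYMES, active_enzymes)
  h <- 1 - prod(1 - params$mu[active])
  d <- 1 - prod(1 - params$delta[active])
  r <- if (params$mode == "tied") 1 - (1 - h) * (1 - d) else h

  S <- matrix(c(1, 0, 0, 0,
                0.5, 0.5, 0, 0,
                0.5, 0, 0.5, 0,
                0, 0.5, 0.5, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(dyad_states(), dyad_states()))
  E <- matrix(c((1 - d)^2, d * (1 - d), (1 - d) * d, d^2,
                0, 1 - r, 0, r,
                0, 0, 1 - r, r,
                0, 0, 0, 1),
              nrow = 4, byrow = TRUE,
              dimnames = list(dyad_states(), dyad_states()))
  S %*% E
}

#' Bisulfite observation (emission) matrix
#'
#' Maps true dyad states to observed analyzable classes under independent
#' per-cytosine observation errors: a methylated C reads methylated with
#' probability `1 - c_over`, an unmethylated C reads methylated with
#' probability `c_fail` (conversion failure). For example a true
#' unmethylated dyad is observed `FULL` with probability `c_fail^2`, and a
#' true upper-hemimethylated dyad with probability `(1 - c_over) * c_fail`.
#'
#' @param params A [dnmt_params()] object (uses `c_fail`, `c_over`).
#' @return 4x4 row-stochastic matrix, rows `U, HU, HL, M`, columns
#'   `UNMETH, HEMI_UPPER, HEMI_LOWER, FULL`.
#' @export
emission_matrix <- function(params) {
  b <- params$c_fail          # unmethylated C observed as methylated
  a <- 1 - params$c_over      # methylated C observed as methylated
  per_state <- function(up_meth, lo_meth) {
    pu <- if (up_meth) a else b
    pl <- if (lo_meth) a else b
    c((1 - pu) * (1 - pl), pu * (1 - pl), (1 - pu) * pl, pu * pl)
  }
  E <- rbind(U = per_state(FALSE, FALSE),
             HU = per_state(TRUE, FALSE),
             HL = per_state(FALSE, TRUE),
             M = per_state(TRUE, TRUE))
  colnames(E) <- analyzable_classes()
  E
}

#' Dyad-state distribution after g generations
#'
#' Propagates `pi0` through `g` applications of the one-generation
#' transition matrix (`g = 0` returns `pi0`). Non-integer `g` (used when
#' generation counts are fitted) is handled through an eigendecomposition
#' matrix power.
#'
#' @param pi0 Initial distribution over `U, HU, HL, M`.
#' @param params A [dnmt_params()] object.
#' @param active_enzymes Enzymes present.
#' @param g Number of generations (>= 0).
#' @return Named probability vector over the four states.
#' @export
state_distribution <- function(pi0, params, active_enzymes = DNMT_ENZYMES,
                               g = 1) {
  P <- replication_transition(params, active_enzymes)
  stats::setNames(as.numeric(pi0 %*% .mat_pow(P, g)), dyad_states())
}

.mat_pow <- function(P, g) {
  if (g < 0) stop("g must be >= 0", call. = FALSE)
  if (abs(g - round(g)) < 1e-9) {
    g <- round(g)
    out <- diag(nrow(P))
    B <- P
    while (g > 0) {
      if (g %% 2 == 1) out <- out %*% B
      B <- B %*% B
      g <- g %/% 2
    }
    return(out)
  }
  e <- eigen(P)
  M <- Re(e$vectors %*% diag(as.complex(e$values)^g) %*% solve(e$vectors))
  M[M < 0] <- 0
  M / rowSums(M)
}

#' Stationary dyad-state distribution
#'
#' Iterates the chain from `pi0` until the distribution changes by less than
#' `tol` in maximum norm.
#'
#' @inheritParams state_distribution
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(params, active_enzymes = DNMT_ENZYMES,
                                    pi0 = c(0.25, 0.25, 0.25, 0.25),
                                    tol = 1e-10, max_iter = 100000L) {
  P <- replication_transition(params, active_enzymes)
  pi <- as.numeric(pi0)
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi %*% P)
    if (max(abs(nxt - pi)) < tol) {
      return(stats::setNames(nxt, dyad_states()))
    }
    pi <- nxt
  }
  warning("stationary iteration did not converge to tol")
  stats::setNames(pi, dyad_states())
}

#' Joint log-likelihood of observed dyad-class counts
#'
#' Sum over regimes of the multinomial log-likelihood of the analyzable
#' class counts under the predicted class distribution
#' `pi0 %*% P^g %*% E`. Class probabilities are floored at 1e-300 so empty
#' classes never produce `-Inf`. Mutated and unresolved dyads must already
#' be excluded from the counts.
#'
#' @param params A [dnmt_params()] object.
#' @param regimes List of [cell_line_regime()]s.
#' @param count_tables List (parallel to `regimes`) of `dyad_count_table`s
#'   or named count vectors over `UNMETH, HEMI_UPPER, HEMI_LOWER, FULL`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, regimes, count_tables) {
  stopifnot(length(regimes) == length(count_tables))
  E <- emission_matrix(params)
  ll <- 0
  for (k in seq_along(regimes)) {
    rg <- regimes[[k]]
    counts <- .analyzable(count_tables[[k]])
    if (sum(counts) == 0) stop("regime with zero total counts", call. = FALSE)
    pg <- state_distribution(rg$pi0, params, rg$active_enzymes,
                             rg$generations)
    q <- pmax(as.numeric(pg %*% E), 1e-300)
    q <- q / sum(q)
    ll <- ll + stats::dmultinom(counts, prob = q, log = TRUE)
  }
  ll
}
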