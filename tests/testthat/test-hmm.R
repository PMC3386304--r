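test_that("transition matrix reduces to pure passive dilution without enzymes", {
  P <- replication_transition(dnmt_params())
  expect_equal(unname(P["M", ]), c(0, 0.5, 0.5, 0))
  expect_equal(unname(P["HU", ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(P["HL", ]), c(0.5, 0, 0.5, 0))
  expect_equal(unname(P["U", ]), c(1, 0, 0, 0))
})

test_that("perfect maintenance keeps fully methylated dyads forever", {
  p <- dnmt_params(mu = c(Dnmt1 = 1), delta = c(Dnmt1 = 0))
  P <- replication_transition(p, "Dnmt1")
  expect_equal(unname(P["M", ]), c(0, 0, 0, 1))
  pi <- state_distribution(c(0, 0, 0, 1), p, "Dnmt1", g = 50)
  expect_equal(unname(pi), c(0, 0, 0, 1))
})

test_that("transition entries match a per-strand enumeration oracle", {
  # enumerate segregation outcome x per-cytosine Bernoulli outcomes
  mu_star <- 0.9; d_star <- 0.1
  p <- dnmt_params(mu = c(Dnmt1 = mu_star), delta = c(Dnmt1 = d_star))
  P <- replication_transition(p, "Dnmt1")
  oracle <- matrix(0, 4, 4, dimnames = list(dyad_states(), dyad_states()))
  seg <- list(U = list(c("U", 1)),
              HU = list(c("U", 0.5), c("HU", 0.5)),
              HL = list(c("U", 0.5), c("HL", 0.5)),
              M = list(c("HU", 0.5), c("HL", 0.5)))
  enz <- function(state) {
    if (state == "U") {
      list(c("U", (1 - d_star)^2), c("HU", d_star * (1 - d_star)),
           c("HL", (1 - d_star) * d_star), c("M", d_star^2))
    } else if (state == "HU") {
      list(c("HU", 1 - mu_star), c("M", mu_star))
    } else if (state == "HL") {
      list(c("HL", 1 - mu_star), c("M", mu_star))
    } else list(c("M", 1))
  }
  for (from in dyad_states()) {
    for (s1 in seg[[from]]) {
      for (s2 in enz(s1[1])) {
        oracle[from, s2[1]] <- oracle[from, s2[1]] +
          as.numeric(s1[2]) * as.numeric(s2[2])
      }
    }
  }
  expect_equal(P, oracle)
})

test_that("emission matrix matches hand arithmetic and the identity limit", {
  expect_equal(emission_matrix(dnmt_params()),
               diag(4), ignore_attr = TRUE)
  E <- emission_matrix(dnmt_params(c_fail = 0.011))
  expect_equal(E["U", "FULL"], 0.011^2)
  E2 <- emission_matrix(dnmt_params(c_fail = 0.01, c_over = 0.05))
  expect_equal(E2["HU", "FULL"], 0.95 * 0.01)
  expect_equal(E2["HU", "UNMETH"], 0.05 * 0.99)
})

test_that("all transition and emission rows are stochastic for random parameters", {
  set.seed(17)
  for (i in 1:250) {
    mu <- setNames(runif(3), c("Dnmt1", "Dnmt3a", "Dnmt3b"))
    delta <- setNames(runif(3), names(mu))
    mode <- sample(c("free", "tied"), 1)
    p <- dnmt_params(mu, delta, mode = mode,
                     c_fail = runif(1, 0, 0.2), c_over = runif(1, 0, 0.2))
    active <- sample(names(mu), sample(1:3, 1))
    P <- replication_transition(p, active)
    E <- emission_matrix(p)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_lt(max(abs(rowSums(E) - 1)), 1e-12)
    expect_true(all(P >= 0 & P <= 1) && all(E >= 0 & E <= 1))
  }
})

test_that("without enzymes the methylation level halves every generation", {
  p <- dnmt_params()
  for (g in 0:12) {
    pi <- state_distribution(c(0, 0, 0, 1), p, g = g)
    lev <- 0.5 * (pi[["HU"]] + pi[["HL"]]) + pi[["M"]]
    expect_equal(lev, 2^-g)
  }
})

test_that("long-run distribution matches the stationary left eigenvector", {
  p <- dnmt_params(mu = c(Dnmt1 = 0.7, Dnmt3a = 0.2),
                   delta = c(Dnmt1 = 0.15, Dnmt3b = 0.05))
  P <- replication_transition(p)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i]); v <- v / sum(v)
  pi <- state_distribution(c(1, 0, 0, 0), p, g = 500)
  expect_lt(max(abs(pi - v)), 1e-8)
  expect_lt(max(abs(stationary_distribution(p) - v)), 1e-8)
})

test_that("strand symmetry: predictions never distinguish HU from HL", {
  p <- dnmt_params(mu = c(Dnmt1 = 0.8, Dnmt3a = 0.1),
                   delta = c(Dnmt1 = 0.3, Dnmt3b = 0.2), c_fail = 0.01)
  P <- replication_transition(p)
  perm <- c(1, 3, 2, 4)   # swap HU and HL
  expect_equal(unname(P[perm, perm]), unname(P))
  E <- emission_matrix(p)
  expect_equal(unname(E[perm, perm]), unname(E))
  pi <- state_distribution(c(0.4, 0.1, 0.1, 0.4), p, g = 7)
  expect_equal(pi[["HU"]], pi[["HL"]])
})

test_that("stationary methylation is monotone in every efficiency", {
  level <- function(mu1, d1) {
    p <- dnmt_params(mu = c(Dnmt1 = mu1, Dnmt3a = 0.1),
                     delta = c(Dnmt1 = d1, Dnmt3b = 0.05))
    pi <- stationary_distribution(p)
    0.5 * (pi[["HU"]] + pi[["HL"]]) + pi[["M"]]
  }
  mus <- seq(0.1, 0.9, by = 0.2)
  lv_mu <- vapply(mus, level, numeric(1), d1 = 0.1)
  expect_true(all(diff(lv_mu) >= -1e-12))
  lv_d <- vapply(mus, function(d) level(0.5, d), numeric(1))
  expect_true(all(diff(lv_d) >= -1e-12))
})

test_that("tied and free modes coincide when all de novo rates are zero", {
  mu <- c(Dnmt1 = 0.6, Dnmt3a = 0.3, Dnmt3b = 0.2)
  free <- dnmt_params(mu, mode = "free")
  tied <- dnmt_params(mu, mode = "tied")
  expect_equal(replication_transition(free), replication_transition(tied))
})

test_that("likelihood equals brute-force hidden-path enumeration for small g", {
  p <- dnmt_params(mu = c(Dnmt1 = 0.8, Dnmt3a = 0.15),
                   delta = c(Dnmt1 = 0.25, Dnmt3b = 0.1),
                   c_fail = 0.01, c_over = 0.002)
  counts <- as_dyad_count_table(c(UNMETH = 40, HEMI_UPPER = 15,
                                  HEMI_LOWER = 12, FULL = 133))
  for (g in c(1, 3, 5)) {
    rg <- cell_line_regime("toy", c("Dnmt1", "Dnmt3a", "Dnmt3b"), g,
                           c(0.1, 0.15, 0.15, 0.6))
    expect_lt(abs(log_likelihood(p, list(rg), list(counts)) -
                    oracle_loglik(p, list(rg), list(counts))), 1e-9)
  }
})

test_that("likelihood is maximal at the exact class proportions", {
  p <- dnmt_params(mu = c(Dnmt1 = 0.9), delta = c(Dnmt1 = 0.2),
                   c_fail = 0.01)
  rg <- cell_line_regime("toy", "Dnmt1", 10, c(0.05, 0.05, 0.05, 0.85))
  q <- as.numeric(state_distribution(rg$pi0, p, "Dnmt1", 10) %*%
                    emission_matrix(p))
  counts <- as_dyad_count_table(setNames(round(q * 100000),
                                         analyzable_classes()))
  ll0 <- log_likelihood(p, list(rg), list(counts))
  for (shift in c(-0.05, 0.05)) {
    p2 <- dnmt_params(mu = c(Dnmt1 = 0.9 + shift),
                      delta = c(Dnmt1 = 0.2), c_fail = 0.01)
    p3 <- dnmt_params(mu = c(Dnmt1 = 0.9),
                      delta = c(Dnmt1 = 0.2 + shift), c_fail = 0.01)
    expect_gt(ll0, log_likelihood(p2, list(rg), list(counts)))
    expect_gt(ll0, log_likelihood(p3, list(rg), list(counts)))
  }
})

test_that("empty classes stay finite through probability flooring", {
  p <- dnmt_params(mu = c(Dnmt1 = 1), delta = c(Dnmt1 = 0))
  rg <- cell_line_regime("toy", "Dnmt1", 5, c(0, 0, 0, 1))
  counts <- as_dyad_count_table(c(UNMETH = 3, HEMI_UPPER = 0,
                                  HEMI_LOWER = 0, FULL = 97))
  expect_true(is.finite(log_likelihood(p, list(rg), list(counts))))
})
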