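mk_read <- function(id, cls, noncpg = NULL) {
  if (is.null(noncpg))
    noncpg <- data.frame(pos = integer(), strand = character(),
                         call = character())
  structure(list(read_id = id, dyads = setNames(cls, seq_along(cls)),
                 noncpg = noncpg),
            class = "read_calls")
}

test_that("overall methylation weights hemimethylated dyads as one half", {
  ct <- as_dyad_count_table(c(UNMETH = 2, HEMI_UPPER = 1, HEMI_LOWER = 1,
                              FULL = 6))
  expect_equal(overall_methylation(ct), 0.70)
  expect_equal(overall_methylation(c(UNMETH = 0, HEMI_UPPER = 0,
                                     HEMI_LOWER = 0, FULL = 12)), 1.0)
  expect_error(overall_methylation(c(UNMETH = 0, HEMI_UPPER = 0,
                                     HEMI_LOWER = 0, FULL = 0)), "no_data")
  # mutated dyads do not enter the level
  ct2 <- as_dyad_count_table(c(UNMETH = 2, HEMI_UPPER = 1, HEMI_LOWER = 1,
                               FULL = 6, MUT_UPPER = 50))
  expect_equal(overall_methylation(ct2), 0.70)
})

test_that("overall methylation recovers the strand density of a simulation", {
  params <- dnmt_params()
  # independent strand methylation with density p: per dyad
  # P(M)=p^2, P(HU)=P(HL)=p(1-p), P(U)=(1-p)^2, weighted level = p
  set.seed(1)
  p <- 0.63
  n <- 20000
  up <- runif(n) < p
  lo <- runif(n) < p
  counts <- c(UNMETH = sum(!up & !lo), HEMI_UPPER = sum(up & !lo),
              HEMI_LOWER = sum(!up & lo), FULL = sum(up & lo))
  expect_lt(abs(overall_methylation(counts) - p),
            4 * sqrt(p * (1 - p) / (2 * n)))
})

test_that("hemi fraction definitions are distinct and correct", {
  ct <- as_dyad_count_table(c(UNMETH = 4, HEMI_UPPER = 1, HEMI_LOWER = 1,
                              FULL = 6))
  expect_equal(as.numeric(hemi_fraction(ct)), 2 / 8)
  expect_equal(attr(hemi_fraction(ct), "split"), c(upper = 1, lower = 1))
  lvl <- overall_methylation(ct)
  expect_equal(as.numeric(hemi_fraction(ct, of = "level")),
               (2 / 12) / lvl)
  all_hemi <- as_dyad_count_table(c(UNMETH = 0, HEMI_UPPER = 2,
                                    HEMI_LOWER = 1, FULL = 0))
  expect_equal(as.numeric(hemi_fraction(all_hemi)), 1.0)
  expect_error(hemi_fraction(as_dyad_count_table(c(UNMETH = 5,
                                                   HEMI_UPPER = 0,
                                                   HEMI_LOWER = 0,
                                                   FULL = 0))),
               "no_methylation")
})

test_that("read categories follow the stated precedence and sum to one", {
  reads <- list(
    mk_read("a", c("FULL", "UNMETH", "FULL")),          # full_only
    mk_read("b", c("HEMI_UPPER", "HEMI_LOWER", "UNMETH")), # dispersed
    mk_read("c", c("FULL", "HEMI_UPPER")),              # full_and_hemi
    mk_read("d", c("HEMI_LOWER", "UNMETH")),            # hemi_only
    mk_read("e", c("UNMETH", "UNMETH")),                # unmeth_only
    mk_read("f", c("MUT_UPPER", "UNRESOLVED"))          # dropped
  )
  rc <- read_categories(reads)
  expect_equal(sum(rc), 1)
  expect_equal(attr(rc, "n"), 5L)
  expect_equal(unname(rc[c("full_only", "dispersed_hemi", "full_and_hemi",
                           "hemi_only", "unmeth_only")]),
               rep(0.2, 5))
  # dispersed wins over full_and_hemi
  rc2 <- read_categories(list(mk_read("g", c("FULL", "HEMI_UPPER",
                                             "HEMI_LOWER"))))
  expect_equal(unname(rc2["dispersed_hemi"]), 1)
})

test_that("position summary gives indicator fractions and drops unresolved", {
  reads <- list(mk_read("a", c("FULL", "UNMETH")),
                mk_read("b", c("FULL", "UNRESOLVED")))
  ps <- position_summary(reads)
  expect_equal(ps$M, c(1, 0))
  expect_equal(ps$U, c(0, 1))
  expect_equal(ps$n, c(2L, 1L))
})

test_that("non-CpG significance testing matches exact binomial tails", {
  counts <- data.frame(pos = c(1, 2, 3), strand = "upper",
                       meth = c(5, 50, 2), unmeth = c(450, 450, 10))
  res <- noncpg_levels(counts, background = 0.011, q = 0.05,
                       min_coverage = 20)
  # position 1: level == background -> not significant
  expect_false(res$significant[1])
  # position 2: 50/500 = 10% vs 1.1% -> overwhelming evidence
  expect_true(res$significant[2])
  expect_lt(res$p_value[2], 1e-10)
  # oracle: one-sided exact binomial tail with BH over the two tested rows
  p_oracle <- c(binom.test(5, 455, 0.011, "greater")$p.value,
                binom.test(50, 500, 0.011, "greater")$p.value)
  expect_equal(res$p_value[1:2], p_oracle)
  expect_equal(res$q_value[1:2], p.adjust(p_oracle, "BH"))
  # position 3 is below coverage: flagged, untested
  expect_true(res$low_coverage[3])
  expect_true(is.na(res$p_value[3]))
})

test_that("CpA bins close the gapped level grouping and count positive reads", {
  nc_pos <- data.frame(pos = 1L, strand = "upper", call = "METH")
  nc_neg <- data.frame(pos = 1L, strand = "upper", call = "UNMETH")
  reads <- list(
    mk_read("a", c("FULL", rep("UNMETH", 3)), nc_neg),   # level 0.25 -> low
    mk_read("b", c("FULL", "FULL", "UNMETH", "UNMETH"), nc_pos), # 0.5 mid
    mk_read("c", rep("FULL", 4), nc_pos)                 # 1.0 -> high
  )
  cb <- cpa_bins(reads)
  expect_equal(cb$n_reads, c(1L, 1L, 1L))
  expect_equal(cb$fraction, c(0, 1, 1))
})

test_that("phi coefficient hits the exact values for co- and anti-methylation", {
  nc <- function(m) data.frame(pos = 1L, strand = "upper",
                               call = if (m) "METH" else "UNMETH")
  co <- c(lapply(1:20, function(i) mk_read(paste0("m", i), "FULL", nc(TRUE))),
          lapply(1:20, function(i) mk_read(paste0("u", i), "UNMETH",
                                           nc(FALSE))))
  res <- comethylation_matrix(co, min_pairs = 30)
  expect_equal(res$phi, 1.0)
  anti <- c(lapply(1:20, function(i) mk_read(paste0("m", i), "FULL",
                                             nc(FALSE))),
            lapply(1:20, function(i) mk_read(paste0("u", i), "UNMETH",
                                             nc(TRUE))))
  expect_equal(comethylation_matrix(anti, min_pairs = 30)$phi, -1.0)
  # independent columns: phi near zero
  set.seed(11)
  ind <- lapply(1:1500, function(i) {
    mk_read(paste0("r", i), sample(c("FULL", "UNMETH"), 1),
            nc(runif(1) < 0.5))
  })
  phi <- comethylation_matrix(ind, min_pairs = 30)$phi
  expect_lt(abs(phi), 2 / sqrt(1500))
  # degenerate column -> NA
  degen <- lapply(1:40, function(i) mk_read(paste0("d", i), "FULL", nc(TRUE)))
  expect_true(is.na(comethylation_matrix(degen, min_pairs = 30)$phi))
})

test_that("hemimethylated dyads count strand-locally in co-methylation", {
  nc <- function(m) data.frame(pos = 1L, strand = "upper",
                               call = if (m) "METH" else "UNMETH")
  # CpA methylation tracks upper-strand hemimethylation exactly
  reads <- c(lapply(1:20, function(i) mk_read(paste0("h", i), "HEMI_UPPER",
                                              nc(TRUE))),
             lapply(1:20, function(i) mk_read(paste0("l", i), "HEMI_LOWER",
                                              nc(FALSE))))
  expect_equal(comethylation_matrix(reads, min_pairs = 30)$phi, 1.0)
})

test_that("single-CpA fraction matches counts and the truncated binomial", {
  nc_k <- function(k, total = 5) {
    data.frame(pos = seq_len(total), strand = "upper",
               call = c(rep("METH", k), rep("UNMETH", total - k)))
  }
  reads <- list(mk_read("a", "FULL", nc_k(1)),
                mk_read("b", "FULL", nc_k(2)),
                mk_read("c", "FULL", nc_k(1)))
  expect_equal(single_cpa_fraction(reads), 2 / 3)
  expect_equal(single_cpa_fraction(reads[c(1, 3)]), 1.0)
  expect_error(single_cpa_fraction(list(mk_read("d", "FULL", nc_k(0)))),
               "no_data")

  # independent per-position probability p over m sites: the expected
  # single-positive share is the truncated binomial P(X = 1 | X >= 1)
  set.seed(8)
  p <- 0.03; m <- 30; n <- 4000
  ks <- rbinom(n, m, p)
  reads2 <- lapply(which(ks > 0), function(i)
    mk_read(paste0("r", i), "FULL", nc_k(ks[i], m)))
  expected <- dbinom(1, m, p) / (1 - dbinom(0, m, p))
  got <- single_cpa_fraction(reads2)
  se <- sqrt(expected * (1 - expected) / length(reads2))
  expect_lt(abs(got - expected), 4 * se)
})
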