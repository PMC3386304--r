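# Independent oracles used across the suite. These deliberately re-derive
# expected values from first principles rather than calling the package's
# own code paths.

# --- dyad-class oracle -------------------------------------------------
# Built generatively: enumerate genomic dyad state x CpG->TpG mutation x
# faithful bisulfite readout (error-free sequencing), record the resulting
# base quadruple and its class; quadruples outside the generated set fall
# back on the mutation A-signature (guanines are bisulfite-inert, so an A
# opposite an expected G can only be a genomic transition) and otherwise
# are unresolvable.
oracle_dyad_map <- local({
  map <- list()
  put <- function(q, cls) {
    key <- paste(q, collapse = "")
    map[[key]] <<- cls
  }
  meth_cfg <- list(U = c(FALSE, FALSE), HU = c(TRUE, FALSE),
                   HL = c(FALSE, TRUE), M = c(TRUE, TRUE))
  cls_of <- c(U = "UNMETH", HU = "HEMI_UPPER", HL = "HEMI_LOWER", M = "FULL")
  for (nm in names(meth_cfg)) {
    m <- meth_cfg[[nm]]
    put(c(if (m[1]) "C" else "T", "G", "G", if (m[2]) "C" else "T"),
        cls_of[[nm]])
  }
  for (l2 in c("C", "T")) put(c("T", "G", "A", l2), "MUT_UPPER")
  for (u1 in c("C", "T")) put(c(u1, "A", "G", "T"), "MUT_LOWER")
  map
})

oracle_dyad_class <- function(u1, u2, l1, l2) {
  hit <- oracle_dyad_map[[paste(c(u1, u2, l1, l2), collapse = "")]]
  if (!is.null(hit)) return(hit)
  up_sig <- identical(l1, "A")
  lo_sig <- identical(u2, "A")
  if (up_sig && !lo_sig) return("MUT_UPPER")
  if (lo_sig && !up_sig) return("MUT_LOWER")
  "UNRESOLVED"
}

# --- brute-force hidden-path likelihood --------------------------------
# Marginal observed-class distribution of one dyad by summing over all
# 4^(g+1) hidden state paths, then the multinomial log-pmf of the counts.
oracle_loglik <- function(params, regimes, count_tables) {
  ll <- 0
  for (k in seq_along(regimes)) {
    rg <- regimes[[k]]
    P <- replication_transition(params, rg$active_enzymes)
    E <- emission_matrix(params)
    g <- rg$generations
    q <- numeric(4)
    paths <- as.matrix(expand.grid(rep(list(1:4), g + 1)))
    for (r in seq_len(nrow(paths))) {
      p <- rg$pi0[paths[r, 1]]
      if (g > 0) for (t in seq_len(g)) {
        p <- p * P[paths[r, t], paths[r, t + 1]]
      }
      q <- q + p * E[paths[r, g + 1], ]
    }
    counts <- unclass(count_tables[[k]])[analyzable_classes()]
    ll <- ll + dmultinom(counts, prob = q, log = TRUE)
  }
  ll
}

# --- plain-R affine-gap alignment score --------------------------------
# Independent Gotoh implementation (score only), bisulfite-aware scoring.
oracle_align_score <- function(ref, read, match = 1, mismatch = -2,
                               gap_open = -4, gap_extend = -1) {
  rb <- strsplit(ref, "")[[1]]
  qb <- strsplit(read, "")[[1]]
  n <- length(rb); m <- length(qb)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (rb[i - 1] == qb[j - 1] ||
               (rb[i - 1] == "C" && qb[j - 1] == "T")) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- shared fixtures ---------------------------------------------------
all_dnmts <- c("Dnmt1", "Dnmt3a", "Dnmt3b")

# bisulfite-convert a strand given per-position methylation (deterministic,
# error-free): every unmethylated C reads T
convert_strand <- function(bases, meth) {
  out <- bases
  out[bases == "C" & !meth] <- "T"
  out
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# assemble a noiseless hairpin read for a given reference and dyad states
make_clean_read <- function(ref, states) {
  ub <- strsplit(ref$upper_seq, "")[[1]]
  lb <- strsplit(chartr("ACGT", "TGCA", ref$upper_seq), "")[[1]]
  n <- length(ub)
  um <- rep(FALSE, n); lm <- rep(FALSE, n)
  um[ref$dyad_pos] <- states %in% c("HU", "M")
  lm[ref$dyad_pos + 1L] <- states %in% c("HL", "M")
  up <- convert_strand(ub, um)
  lo <- convert_strand(lb, lm)
  lkb <- strsplit(ref$linker_seq, "")[[1]]
  lk <- lkb
  lk[ref$linker_marked] <- "T"       # fully converted linker
  paste(c(up, lk, rev(lo)), collapse = "")
}
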