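#' Simulate dyad-state populations across cell generations
#'
#' Evolves each molecule's dyads independently under the one-generation
#' chain of [replication_transition()]: initial states are drawn from the
#' regime's `pi0`, then propagated for `generations` steps. Fully
#' deterministic given `seed`.
#'
#' @param params A [dnmt_params()] object.
#' @param regime A [cell_line_regime()].
#' @param n_molecules Number of molecules.
#' @param n_dyads Dyads per molecule.
#' @param seed Mandatory RNG seed.
#' @return List with `states` (`n_molecules x n_dyads` character matrix over
#'   `U, HU, HL, M`) and `trajectory` (data.frame of per-generation state
#'   frequencies, generation 0 = initial draw).
#' @export
simulate_states <- function(params, regime, n_molecules, n_dyads, seed) {
  stopifnot(inherits(regime, "cell_line_regime"), !missing(seed))
  P <- replication_transition(params, regime$active_enzymes)
  g <- regime$generations
  if (abs(g - round(g)) > 1e-9)
    stop("simulate_states needs an integer generation count", call. = FALSE)
  g <- as.integer(round(g))
  n <- n_molecules * n_dyads

  .with_seed(seed, {
    s <- sample.int(4L, n, replace = TRUE, prob = regime$pi0)
    traj <- matrix(NA_real_, g + 1L, 4L)
    traj[1L, ] <- tabulate(s, 4L) / n
    if (g > 0) for (t in seq_len(g)) {
      s_new <- s
      for (from in 1:4) {
        idx <- which(s == from)
        if (length(idx))
          s_new[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[from, ])
      }
      s <- s_new
      traj[t + 1L, ] <- tabulate(s, 4L) / n
    }
    states <- matrix(dyad_states()[s], n_molecules, n_dyads)
    trajectory <- data.frame(generation = 0:g, traj)
    names(trajectory)[2:5] <- dyad_states()
    list(states = states, trajectory = trajectory)
  })
}

#' Sample observed dyad classes from true states
#'
#' Applies the bisulfite observation layer of [emission_matrix()]
#' stochastically, dyad by dyad.
#'
#' @param states Character matrix (or vector) of true states.
#' @param params A [dnmt_params()] (uses `c_fail`, `c_over`).
#' @param seed Mandatory RNG seed.
#' @return Object shaped like `states` with entries in
#'   `UNMETH, HEMI_UPPER, HEMI_LOWER, FULL`.
#' @export
sample_observed_classes <- function(states, params, seed) {
  E <- emission_matrix(params)
  s <- match(as.vector(states), dyad_states())
  .with_seed(seed, {
    out <- integer(length(s))
    for (from in 1:4) {
      idx <- which(s == from)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = E[from, ])
    }
    res <- analyzable_classes()[out]
    if (is.matrix(states)) res <- matrix(res, nrow(states), ncol(states))
    res
  })
}

#' Simulate a dyad-class count table for one regime
#'
#' Convenience wrapper: [simulate_states()] then
#' [sample_observed_classes()], tabulated as a `dyad_count_table`.
#'
#' @inheritParams simulate_states
#' @param amplicon Amplicon label.
#' @return A `dyad_count_table` with attribute `truth` (the true state
#'   frequencies).
#' @export
simulate_count_table <- function(params, regime, n_molecules, n_dyads,
                                 seed, amplicon = "synthetic") {
  st <- simulate_states(params, regime, n_molecules, n_dyads, seed)
  obs <- sample_observed_classes(st$states, params, seed + 1L)
  counts <- vapply(analyzable_classes(), function(k) sum(obs == k),
                   integer(1))
  out <- as_dyad_count_table(counts, line = regime$line_name,
                             amplicon = amplicon)
  attr(out, "truth") <- table(factor(st$states, dyad_states())) /
    length(st$states)
  out
}

#' Simulate non-CpG (CpA) methylation states coupled to CpG methylation
#'
#' Each registered non-CpG cytosine of each molecule is methylated with its
#' base probability `p_pos`, multiplied on the odds scale by `kappa` when
#' the nearest CpG on the same strand is methylated (strand-locally: upper
#' hemimethylation or full methylation for an upper-strand cytosine).
#' Probabilities that would exceed 1 are clipped with a warning.
#'
#' @param states Character matrix of true dyad states from
#'   [simulate_states()] (`n_molecules x n_dyads`).
#' @param ref An `amplicon_reference` whose dyads (in registry order) map
#'   onto the columns of `states`; its non-CpG registry defines the sites.
#' @param p_pos Base methylation probability per non-CpG site: scalar or
#'   vector along `ref$noncpg` rows.
#' @param kappa Odds multiplier when the nearest same-strand CpG is
#'   methylated (1 = no coupling).
#' @param seed Mandatory RNG seed.
#' @return Logical matrix `n_molecules x nrow(ref$noncpg)`; `TRUE` =
#'   methylated.
#' @export
simulate_noncpg <- function(states, ref, p_pos, kappa = 1, seed) {
  nc <- ref$noncpg
  if (ncol(states) != length(ref$dyad_pos))
    stop("states columns must match the reference dyad registry",
         call. = FALSE)
  p_pos <- rep_len(p_pos, nrow(nc))
  .check_prob(p_pos, "p_pos")
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)

  # nearest CpG dyad (by upper-strand coordinate) for every non-CpG site
  nearest <- vapply(nc$pos, function(p) {
    which.min(abs(ref$dyad_pos - p))
  }, integer(1))

  .with_seed(seed, {
    out <- matrix(FALSE, nrow(states), nrow(nc))
    for (j in seq_len(nrow(nc))) {
      st <- states[, nearest[j]]
      meth_near <- if (nc$strand[j] == "upper") st %in% c("HU", "M")
                   else st %in% c("HL", "M")
      odds <- p_pos[j] / (1 - p_pos[j])
      p_hi <- (kappa * odds) / (1 + kappa * odds)
      if (p_hi > 1) { warning("clipping coupled probability at 1"); p_hi <- 1 }
      p <- ifelse(meth_near, p_hi, p_pos[j])
      out[, j] <- stats::runif(nrow(states)) < p
    }
    out
  })
}

#' Render synthetic hairpin-bisulfite reads with recorded ground truth
#'
#' Turns simulated dyad states (and optional non-CpG states) into raw
#' hairpin reads: CpG-to-TpG mutations are injected per dyad at
#' `mutation_rate` (strand chosen uniformly; germline-like, placed once per
#' molecule), bisulfite conversion is applied per cytosine (`c_fail`,
#' `c_over` from `params`), the molecule is assembled as
#' upper strand + converted linker + lower strand (5'-3'), uniform
#' substitution sequencing error is added, and each read is emitted in a
#' uniformly random orientation. Deterministic given `seed`.
#'
#' @param states Character matrix of true dyad states
#'   (`n_molecules x n_dyads`, matching `ref$dyad_pos`).
#' @param ref An `amplicon_reference`.
#' @param params A [dnmt_params()] (conversion error rates).
#' @param mutation_rate Per-dyad CpG-to-TpG mutation probability.
#' @param noncpg_states Optional logical matrix from [simulate_noncpg()].
#' @param seq_error_rate Per-base substitution error probability.
#' @param seed Mandatory RNG seed.
#' @param fastq Optional path; when given, reads are written as
#'   uncompressed FASTQ (constant quality).
#' @param truth_file Optional path for the truth TSV.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `states` (comma-joined), `mut_strand`
#'   (comma-joined, `.`/`upper`/`lower`), `orientation`).
#' @export
render_reads <- function(states, ref, params, mutation_rate = 0,
                         noncpg_states = NULL, seq_error_rate = 0, seed,
                         fastq = NULL, truth_file = NULL) {
  stopifnot(ncol(states) == length(ref$dyad_pos))
  .check_prob(c(mutation_rate, seq_error_rate), "rates")
  upper_ref <- .chars(ref$upper_seq)
  n <- length(upper_ref)
  lower_ref <- .complement_chr(upper_ref)     # lower strand, ref coordinates
  linker <- .chars(ref$linker_seq)
  linker_unmeth <- seq_along(linker) %in% ref$linker_marked
  nmol <- nrow(states)
  bases <- c("A", "C", "G", "T")

  nc <- ref$noncpg
  .with_seed(seed, {
    reads <- character(nmol)
    mut_rec <- character(nmol)
    orient <- character(nmol)
    for (m in seq_len(nmol)) {
      up <- upper_ref
      lo <- lower_ref
      up_meth <- rep(FALSE, n)
      lo_meth <- rep(FALSE, n)
      st <- states[m, ]
      up_meth[ref$dyad_pos] <- st %in% c("HU", "M")
      lo_meth[ref$dyad_pos + 1L] <- st %in% c("HL", "M")
      if (!is.null(noncpg_states) && nrow(nc)) {
        for (j in which(noncpg_states[m, ])) {
          if (nc$strand[j] == "upper") up_meth[nc$pos[j]] <- TRUE
          else lo_meth[nc$pos[j]] <- TRUE
        }
      }
      # germline-like CpG->TpG mutations, one strand per mutated dyad
      mut <- rep(".", length(ref$dyad_pos))
      hit <- stats::runif(length(ref$dyad_pos)) < mutation_rate
      for (d in which(hit)) {
        i <- ref$dyad_pos[d]
        if (stats::runif(1) < 0.5) {
          mut[d] <- "upper"
          up[i] <- "T"; lo[i] <- "A"
          up_meth[i] <- FALSE
        } else {
          mut[d] <- "lower"
          lo[i + 1L] <- "T"; up[i + 1L] <- "A"
          lo_meth[i + 1L] <- FALSE
        }
      }
      bs <- function(b, meth) {
        isC <- b == "C"
        u <- stats::runif(length(b))
        conv <- isC & !meth & (u >= params$c_fail)        # converted
        over <- isC & meth & (u < params$c_over)          # over-converted
        b[conv | over] <- "T"
        b
      }
      up_bs <- bs(up, up_meth)
      lo_bs <- bs(lo, lo_meth)
      lk_bs <- linker
      lk_conv <- linker_unmeth & linker == "C" &
        (stats::runif(length(linker)) >= params$c_fail)
      lk_bs[lk_conv] <- "T"
      read <- c(up_bs, lk_bs, rev(lo_bs))   # lower strand written 5'-3'
      err <- which(stats::runif(length(read)) < seq_error_rate)
      for (e in err) read[e] <- sample(setdiff(bases, read[e]), 1L)
      read <- .collapse(read)
      if (stats::runif(1) < 0.5) {
        read <- .revcomp(read)
        orient[m] <- "reverse"
      } else orient[m] <- "forward"
      reads[m] <- read
      mut_rec[m] <- paste(mut, collapse = ",")
    }
    ids <- sprintf("mol_%06d", seq_len(nmol))
    names(reads) <- ids
    truth <- data.frame(
      read_id = ids,
      states = apply(states, 1, paste, collapse = ","),
      mut_strand = mut_rec,
      orientation = orient,
      stringsAsFactors = FALSE)
    if (!is.null(fastq)) {
      qual <- vapply(nchar(reads), function(w) .collapse(rep("I", w)), "")
      writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)),
                 fastq)
    }
    if (!is.null(truth_file))
      utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate the knockout-panel study design
#'
#' Builds the four informative Dnmt knockout regimes (Dnmt1-KO, Dnmt3a-KO,
#' Dnmt3b-KO and the Dnmt3a/3b double KO), all started from the wild-type
#' state distribution, simulates a wild-type sample (for the observed
#' initial class proportions) and one dyad-class count table per knockout
#' regime.
#'
#' @param params Generating [dnmt_params()].
#' @param n_molecules Molecules per regime (default 5000).
#' @param n_dyads Dyads per molecule (default 4; so 20000 dyads per regime
#'   at the defaults).
#' @param generations Transient-phase generations for every knockout line
#'   (default 20).
#' @param seed Mandatory RNG seed.
#' @param regime_names Optional subset of
#'   `c("Dnmt1KO", "Dnmt3aKO", "Dnmt3bKO", "DKO")` to simulate.
#' @return List with `count_tables`, `regimes` (both named by line, with
#'   `pi0` set to the observed wild-type class proportions), `wt_counts`,
#'   `wt_pi` (the true wild-type state distribution) and `truth`
#'   (per-regime true state frequencies).
#' @export
simulate_ko_panel <- function(params, n_molecules = 5000L, n_dyads = 4L,
                              generations = 20L, seed,
                              regime_names = c("Dnmt1KO", "Dnmt3aKO",
                                               "Dnmt3bKO", "DKO")) {
  designs <- list(
    Dnmt1KO  = c("Dnmt3a", "Dnmt3b"),
    Dnmt3aKO = c("Dnmt1", "Dnmt3b"),
    Dnmt3bKO = c("Dnmt1", "Dnmt3a"),
    DKO      = "Dnmt1")
  regime_names <- match.arg(regime_names, several.ok = TRUE)
  wt_pi <- stationary_distribution(params, DNMT_ENZYMES)

  # observed wild-type sample supplies pi0 as class proportions
  wt_regime <- cell_line_regime("WT", DNMT_ENZYMES, 1, wt_pi)
  wt_states <- .with_seed(seed, {
    s <- sample.int(4L, n_molecules * n_dyads, replace = TRUE, prob = wt_pi)
    matrix(dyad_states()[s], n_molecules, n_dyads)
  })
  wt_obs <- sample_observed_classes(wt_states, params, seed + 11L)
  wt_counts <- as_dyad_count_table(
    vapply(analyzable_classes(), function(k) sum(wt_obs == k), integer(1)),
    line = "WT")
  pi0_obs <- as.numeric(.analyzable(wt_counts) / sum(.analyzable(wt_counts)))
  pi0_obs <- pi0_obs / sum(pi0_obs)

  count_tables <- list()
  regimes <- list()
  truth <- list()
  for (i in seq_along(regime_names)) {
    nm <- regime_names[i]
    gen_regime <- cell_line_regime(nm, designs[[nm]], generations, wt_pi)
    ct <- simulate_count_table(params, gen_regime, n_molecules, n_dyads,
                               seed + 100L * i)
    truth[[nm]] <- attr(ct, "truth")
    count_tables[[nm]] <- ct
    regimes[[nm]] <- cell_line_regime(nm, designs[[nm]], generations,
                                      pi0_obs)
  }
  list(count_tables = count_tables, regimes = regimes,
       wt_counts = wt_counts, wt_pi = wt_pi, truth = truth)
}
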