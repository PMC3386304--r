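#' Overall methylation level of a dyad count table
#'
#' Hemimethylated dyads are weighted as half-methylated, fully methylated
#' dyads as fully methylated:
#' `(0.5 * (HU + HL) + M) / (U + HU + HL + M)`.
#' Mutated and unresolved dyads never enter the denominator.
#'
#' @param counts A `dyad_count_table` or a named count vector over the
#'   analyzable classes.
#' @return Level in `[0, 1]`.
#' @export
overall_methylation <- function(counts) {
  k <- .analyzable(counts)
  tot <- sum(k)
  if (tot == 0) stop("no_data: zero analyzable dyads", call. = FALSE)
  (0.5 * (k[["HEMI_UPPER"]] + k[["HEMI_LOWER"]]) + k[["FULL"]]) / tot
}

.analyzable <- function(counts) {
  if (inherits(counts, "dyad_count_table")) counts <- unclass(counts)
  missing <- setdiff(analyzable_classes(), names(counts))
  if (length(missing))
    stop("counts must name classes ", paste(missing, collapse = ", "),
         call. = FALSE)
  counts[analyzable_classes()]
}

#' Hemimethylation fraction
#'
#' Primary definition (`of = "methylated"`): hemimethylated dyads as a share
#' of all methylated dyads, `(HU + HL) / (HU + HL + M)` — the form behind
#' "% of all methylated CpG dyads". The alternative (`of = "level"`) is the
#' hemi share of all analyzable dyads normalized by the weighted overall
#' methylation level; the two must never be mixed in one comparison.
#'
#' @param counts As in [overall_methylation()].
#' @param of `"methylated"` (default) or `"level"`.
#' @return Fraction in `[0, 1]`, plus attribute `split` with the upper/lower
#'   contributions (`split["upper"] + split["lower"]` equals `HU + HL`).
#' @export
hemi_fraction <- function(counts, of = c("methylated", "level")) {
  of <- match.arg(of)
  k <- .analyzable(counts)
  hemi <- k[["HEMI_UPPER"]] + k[["HEMI_LOWER"]]
  if (hemi + k[["FULL"]] == 0)
    stop("no_methylation: no methylated dyads", call. = FALSE)
  val <- if (of == "methylated") {
    hemi / (hemi + k[["FULL"]])
  } else {
    (hemi / sum(k)) / overall_methylation(counts)
  }
  structure(val, split = c(upper = unname(k[["HEMI_UPPER"]]),
                           lower = unname(k[["HEMI_LOWER"]])))
}

#' Per-read distribution of methylated and hemimethylated sites
#'
#' Assigns every read with at least one analyzable dyad to exactly one
#' category, by precedence: `dispersed_hemi` (hemimethylated dyads on both
#' strands in the same molecule), `full_and_hemi`, `full_only`, `hemi_only`,
#' `unmeth_only`. Unmethylated dyads are allowed in every category.
#'
#' @param read_calls_list List of `read_calls`.
#' @return Named fractions over the five categories (sum to 1), with
#'   attribute `n` (number of categorized reads).
#' @export
read_categories <- function(read_calls_list) {
  cats <- c("full_only", "full_and_hemi", "hemi_only", "dispersed_hemi",
            "unmeth_only")
  lab <- vapply(read_calls_list, function(x) {
    d <- x$dyads[x$dyads %in% analyzable_classes()]
    if (!length(d)) return(NA_character_)
    hu <- any(d == "HEMI_UPPER"); hl <- any(d == "HEMI_LOWER")
    fu <- any(d == "FULL")
    if (hu && hl) "dispersed_hemi"
    else if (fu && (hu || hl)) "full_and_hemi"
    else if (fu) "full_only"
    else if (hu || hl) "hemi_only"
    else "unmeth_only"
  }, character(1))
  lab <- lab[!is.na(lab)]
  if (!length(lab)) stop("no_data: no analyzable reads", call. = FALSE)
  out <- vapply(cats, function(k) mean(lab == k), numeric(1))
  structure(out, n = length(lab))
}

#' Per-position dyad class composition
#'
#' For each dyad position, the fractions of unmethylated, hemimethylated
#' (by strand), fully methylated and mutated calls among reads covering the
#' position (unresolved calls are not coverage).
#'
#' @param read_calls_list List of `read_calls`.
#' @return data.frame `pos`, `n`, `U`, `HU`, `HL`, `M`, `MUT`.
#' @export
position_summary <- function(read_calls_list) {
  cls <- unlist(lapply(read_calls_list, `[[`, "dyads"))
  pos <- as.integer(names(cls))
  keep <- cls != "UNRESOLVED"
  cls <- cls[keep]; pos <- pos[keep]
  if (!length(cls)) return(data.frame(pos = integer(), n = integer(),
                                      U = numeric(), HU = numeric(),
                                      HL = numeric(), M = numeric(),
                                      MUT = numeric()))
  group <- function(target) {
    vapply(split(cls %in% target, pos), mean, numeric(1))
  }
  upos <- sort(unique(pos))
  data.frame(pos = upos,
             n = as.integer(table(pos)[as.character(upos)]),
             U = group("UNMETH")[as.character(upos)],
             HU = group("HEMI_UPPER")[as.character(upos)],
             HL = group("HEMI_LOWER")[as.character(upos)],
             M = group("FULL")[as.character(upos)],
             MUT = group(c("MUT_UPPER", "MUT_LOWER"))[as.character(upos)],
             row.names = NULL)
}

#' Tally non-CpG calls per position and strand
#'
#' @param read_calls_list List of `read_calls`.
#' @return data.frame `pos`, `strand`, `meth`, `unmeth` (counts; `OTHER`
#'   calls are dropped).
#' @export
tally_noncpg <- function(read_calls_list) {
  nc <- do.call(rbind, lapply(read_calls_list, `[[`, "noncpg"))
  if (is.null(nc) || !nrow(nc))
    return(data.frame(pos = integer(), strand = character(),
                      meth = integer(), unmeth = integer()))
  nc <- nc[nc$call != "OTHER", , drop = FALSE]
  key <- interaction(nc$pos, nc$strand, drop = TRUE)
  out <- do.call(rbind, lapply(split(nc, key), function(g) {
    data.frame(pos = g$pos[1], strand = g$strand[1],
               meth = sum(g$call == "METH"),
               unmeth = sum(g$call == "UNMETH"))
  }))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position-wise non-CpG methylation levels with significance flags
#'
#' Tests, per (position, strand), whether the observed non-CpG methylation
#' level exceeds the sample's bisulfite conversion background (measured from
#' the linker, typically around 1%), with a one-sided exact binomial test
#' and Benjamini-Hochberg correction across positions at the given FDR.
#' Positions with fewer than `min_coverage` informative reads are flagged
#' `low_coverage` and not tested.
#'
#' @param noncpg_counts data.frame from [tally_noncpg()] (`pos`, `strand`,
#'   `meth`, `unmeth`), or a list of `read_calls` (tallied internally).
#' @param background Conversion-failure rate (1 minus the linker conversion
#'   rate), in `[0, 1]`.
#' @param q FDR threshold (default 0.05).
#' @param min_coverage Minimum reads per position (default 20).
#' @return Input data.frame plus `n`, `level`, `p_value`, `q_value`,
#'   `significant`, `low_coverage`.
#' @export
noncpg_levels <- function(noncpg_counts, background, q = 0.05,
                          min_coverage = 20L) {
  .check_prob(background, "background")
  if (!is.data.frame(noncpg_counts))
    noncpg_counts <- tally_noncpg(noncpg_counts)
  d <- noncpg_counts
  d$n <- d$meth + d$unmeth
  d$level <- ifelse(d$n > 0, d$meth / d$n, NA_real_)
  d$low_coverage <- d$n < min_coverage
  d$p_value <- NA_real_
  testable <- which(!d$low_coverage)
  for (i in testable) {
    d$p_value[i] <- stats::binom.test(d$meth[i], d$n[i], p = background,
                                      alternative = "greater")$p.value
  }
  d$q_value <- NA_real_
  d$q_value[testable] <- stats::p.adjust(d$p_value[testable], method = "BH")
  d$significant <- !is.na(d$q_value) & d$q_value <= q
  d
}

#' Per-read CpG methylation level
#'
#' The 0.5-weighted level over a read's own analyzable dyads (hemimethylated
#' counts half, fully methylated counts one).
#'
#' @param read_calls A `read_calls` object.
#' @return Level in `[0, 1]`, or `NA` without analyzable dyads.
#' @export
read_cpg_level <- function(read_calls) {
  d <- read_calls$dyads[read_calls$dyads %in% analyzable_classes()]
  if (!length(d)) return(NA_real_)
  (0.5 * sum(d %in% c("HEMI_UPPER", "HEMI_LOWER")) + sum(d == "FULL")) /
    length(d)
}

#' CpA methylation by CpG methylation level bin
#'
#' Groups reads by their own CpG methylation level into three bins covering
#' `[0, 0.25]`, `(0.25, 0.70]` and `(0.70, 1]` (a gap-free closure of the
#' conventional 0-25% / 33-66.7% / 75-100% grouping for reads with about
#' four dyads) and reports, per bin, the fraction of reads carrying at least
#' one methylated CpA/non-CpG cytosine.
#'
#' @param read_calls_list List of `read_calls`; reads without analyzable
#'   dyads or without non-CpG calls are skipped.
#' @return data.frame `bin`, `n_reads`, `cpa_positive`, `fraction`.
#' @export
cpa_bins <- function(read_calls_list) {
  lev <- vapply(read_calls_list, read_cpg_level, numeric(1))
  has_nc <- vapply(read_calls_list, function(x) {
    any(x$noncpg$call %in% c("METH", "UNMETH"))
  }, logical(1))
  pos <- vapply(read_calls_list, function(x) any(x$noncpg$call == "METH"),
                logical(1))
  keep <- !is.na(lev) & has_nc
  bin <- cut(lev[keep], breaks = c(0, 0.25, 0.70, 1), include.lowest = TRUE,
             labels = c("low", "mid", "high"))
  out <- data.frame(bin = levels(bin),
                    n_reads = as.integer(table(bin)),
                    cpa_positive = as.integer(tapply(pos[keep], bin, sum,
                                                     default = 0L)))
  out$fraction <- ifelse(out$n_reads > 0, out$cpa_positive / out$n_reads,
                         NA_real_)
  out
}

#' Strand-local co-methylation between non-CpG and CpG positions
#'
#' For every (non-CpG position, CpG dyad) pair on the same strand with at
#' least `min_pairs` reads informative for both, the phi coefficient
#' (Pearson correlation of the binary methylation indicators) across reads.
#' The CpG indicator is strand-local: on the upper strand `FULL` or
#' `HEMI_UPPER` count as methylated, on the lower strand `FULL` or
#' `HEMI_LOWER`. Degenerate columns (all 0 or all 1) yield `NA`.
#'
#' @param read_calls_list List of `read_calls`.
#' @param min_pairs Minimum informative reads per pair (default 30).
#' @return data.frame `noncpg_pos`, `cpg_pos`, `strand`, `n`, `phi`.
#' @export
comethylation_matrix <- function(read_calls_list, min_pairs = 30L) {
  nc_keys <- unique(do.call(rbind, lapply(read_calls_list, function(x)
    x$noncpg[, c("pos", "strand")])))
  if (is.null(nc_keys) || !nrow(nc_keys))
    return(data.frame(noncpg_pos = integer(), cpg_pos = integer(),
                      strand = character(), n = integer(), phi = numeric()))
  dyad_pos <- sort(unique(as.integer(unlist(
    lapply(read_calls_list, function(x) names(x$dyads))))))

  nc_ind <- function(x, p, s) {
    row <- x$noncpg[x$noncpg$pos == p & x$noncpg$strand == s, "call"]
    if (!length(row) || !(row[1] %in% c("METH", "UNMETH"))) return(NA)
    row[1] == "METH"
  }
  cpg_ind <- function(x, p, s) {
    cl <- x$dyads[as.character(p)]
    if (is.na(cl) || !(cl %in% analyzable_classes())) return(NA)
    if (s == "upper") cl %in% c("FULL", "HEMI_UPPER")
    else cl %in% c("FULL", "HEMI_LOWER")
  }

  rows <- list()
  for (k in seq_len(nrow(nc_keys))) {
    p <- nc_keys$pos[k]; s <- nc_keys$strand[k]
    a_all <- vapply(read_calls_list, nc_ind, logical(1), p = p, s = s)
    for (cp in dyad_pos) {
      b_all <- vapply(read_calls_list, cpg_ind, logical(1), p = cp, s = s)
      ok <- !is.na(a_all) & !is.na(b_all)
      n <- sum(ok)
      if (n < min_pairs) next
      a <- a_all[ok]; b <- b_all[ok]
      phi <- if (length(unique(a)) < 2L || length(unique(b)) < 2L) NA_real_
             else stats::cor(as.numeric(a), as.numeric(b))
      rows[[length(rows) + 1L]] <-
        data.frame(noncpg_pos = p, cpg_pos = cp, strand = s, n = n,
                   phi = phi)
    }
  }
  if (!length(rows))
    return(data.frame(noncpg_pos = integer(), cpg_pos = integer(),
                      strand = character(), n = integer(), phi = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of CpA-positive reads with exactly one methylated CpA
#'
#' Among reads with at least one methylated non-CpG cytosine, the fraction
#' carrying exactly one — the signature of sporadic single-site CpA
#' methylation.
#'
#' @param read_calls_list List of `read_calls`.
#' @return Fraction in `(0, 1]`.
#' @export
single_cpa_fraction <- function(read_calls_list) {
  k <- vapply(read_calls_list, function(x) sum(x$noncpg$call == "METH"),
              integer(1))
  k <- k[k >= 1L]
  if (!length(k)) stop("no_data: no CpA-positive reads", call. = FALSE)
  mean(k == 1L)
}

#' Full summary statistics report for one (line, amplicon) sample
#'
#' Bundles the dyad-level and non-CpG statistics into one list and
#' optionally writes them as JSON plus one flat TSV per table.
#'
#' @param read_calls_list List of `read_calls`.
#' @param background Conversion-failure background for [noncpg_levels()].
#' @param line,amplicon Sample labels.
#' @param outdir Optional output directory.
#' @return List with `counts`, `overall_methylation`, `hemi_fraction`,
#'   `hemi_split`, `read_categories`, `position_summary`, `noncpg_levels`,
#'   `cpa_bins`, `comethylation`, `single_cpa_fraction`,
#'   `mutation_fraction`.
#' @export
stats_report <- function(read_calls_list, background, line = "sample",
                         amplicon = "amplicon", outdir = NULL) {
  counts <- dyad_count_table(read_calls_list, line, amplicon)
  hemi <- tryCatch(hemi_fraction(counts), error = function(e) NA_real_)
  rep <- list(
    line = line, amplicon = amplicon,
    counts = stats::setNames(as.integer(counts), names(counts)),
    overall_methylation = overall_methylation(counts),
    hemi_fraction = as.numeric(hemi),
    hemi_split = attr(hemi, "split"),
    read_categories = read_categories(read_calls_list),
    position_summary = position_summary(read_calls_list),
    noncpg_levels = noncpg_levels(read_calls_list, background),
    cpa_bins = cpa_bins(read_calls_list),
    comethylation = comethylation_matrix(read_calls_list),
    single_cpa_fraction = tryCatch(single_cpa_fraction(read_calls_list),
                                   error = function(e) NA_real_),
    mutation_fraction = mutation_fraction(read_calls_list)$fraction
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    scalars <- rep[c("line", "amplicon", "overall_methylation",
                     "hemi_fraction", "single_cpa_fraction",
                     "mutation_fraction")]
    scalars$counts <- as.list(rep$counts)
    scalars$read_categories <- as.list(rep$read_categories)
    jsonlite::write_json(scalars, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tab in c("position_summary", "noncpg_levels", "cpa_bins",
                  "comethylation")) {
      utils::write.table(rep[[tab]], file.path(outdir, paste0(tab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  rep
}
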