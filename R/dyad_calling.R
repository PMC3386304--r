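#' Classify one CpG dyad from its four informative base calls
#'
#' A dyad is read through four strand-local bases: upper strand at the CpG's
#' C (`u_i`) and G (`u_i1`), lower strand at the G-partner (`l_i`) and the
#' lower C (`l_i1`). Guanines are untouched by bisulfite, so an adenine
#' where a G is expected can only arise from a genomic CpG-to-TpG transition
#' on the opposite strand: `l_i = A` marks an upper-strand mutation,
#' `u_i1 = A` a lower-strand one (both signatures at once are treated as
#' unresolvable). With both Gs intact, the two cytosine readouts map
#' C (methylated) / T (converted, unmethylated) to the four analyzable
#' classes. Gaps or any other base combination fall into `UNRESOLVED`.
#'
#' @param u_i,u_i1,l_i,l_i1 Single characters in `A/C/G/T/-`.
#' @return One of [observed_classes()].
#' @examples
#' call_dyad("C", "G", "G", "C")  # FULL
#' call_dyad("T", "G", "A", "T")  # MUT_UPPER
#' @export
call_dyad <- function(u_i, u_i1, l_i, l_i1) {
  mut_up <- identical(l_i, "A")
  mut_lo <- identical(u_i1, "A")
  if (mut_up && mut_lo) return("UNRESOLVED")
  if (mut_up) return("MUT_UPPER")
  if (mut_lo) return("MUT_LOWER")
  if (!identical(l_i, "G") || !identical(u_i1, "G")) return("UNRESOLVED")
  if (identical(u_i, "C") && identical(l_i1, "C")) return("FULL")
  if (identical(u_i, "C") && identical(l_i1, "T")) return("HEMI_UPPER")
  if (identical(u_i, "T") && identical(l_i1, "C")) return("HEMI_LOWER")
  if (identical(u_i, "T") && identical(l_i1, "T")) return("UNMETH")
  "UNRESOLVED"
}

#' Call all dyads and non-CpG cytosines of one read
#'
#' Applies [call_dyad()] at every registered dyad position and, at every
#' registered non-CpG cytosine, calls `METH` for a strand-local C, `UNMETH`
#' for T and `OTHER` for anything else (gap, sequencing error, mutation).
#'
#' @param profile A passing `read_profile` from [extract_read_profile()].
#' @param ref The `amplicon_reference` the profile was aligned to.
#' @return An object of class `read_calls`: `read_id`, `dyads` (character
#'   vector of observed classes named by dyad position), `noncpg`
#'   (data.frame `pos`, `strand`, `call`).
#' @export
call_read <- function(profile, ref) {
  up <- profile$upper_calls
  lo <- profile$lower_calls
  dyads <- vapply(ref$dyad_pos, function(i) {
    call_dyad(up[[i]], up[[i + 1L]], lo[[i]], lo[[i + 1L]])
  }, character(1))
  names(dyads) <- as.character(ref$dyad_pos)

  nc <- ref$noncpg
  if (nrow(nc)) {
    base <- ifelse(nc$strand == "upper", up[nc$pos], lo[nc$pos])
    call <- ifelse(base == "C", "METH", ifelse(base == "T", "UNMETH", "OTHER"))
  } else {
    call <- character(0)
  }
  structure(
    list(read_id = profile$read_id,
         dyads = dyads,
         noncpg = data.frame(pos = nc$pos, strand = nc$strand, call = call,
                             stringsAsFactors = FALSE)),
    class = "read_calls")
}

#' Fraction of mutated CpG dyads in a read collection
#'
#' Mutated dyads (genomic CpG-to-TpG on either strand) as a fraction of all
#' covered dyads (everything except `UNRESOLVED`), overall and per position.
#' Repetitive elements can carry heavy loads (up to 44% in SINE B1-like
#' elements), which single-strand bisulfite sequencing would miscount as
#' unmethylated.
#'
#' @param read_calls_list List of `read_calls` from [call_read()].
#' @return List with `fraction` and `per_position` (data.frame `pos`,
#'   `mutated`, `covered`, `fraction`).
#' @export
mutation_fraction <- function(read_calls_list) {
  cls <- unlist(lapply(read_calls_list, `[[`, "dyads"))
  pos <- as.integer(names(cls))
  covered <- cls != "UNRESOLVED"
  if (!any(covered)) stop("no_data: no covered dyads", call. = FALSE)
  mut <- cls %in% c("MUT_UPPER", "MUT_LOWER")
  df <- data.frame(pos = pos[covered], mutated = as.integer(mut[covered]))
  per <- stats::aggregate(mutated ~ pos, data = df, FUN = sum)
  per$covered <- as.integer(table(df$pos)[as.character(per$pos)])
  per$fraction <- per$mutated / per$covered
  list(fraction = sum(mut) / sum(covered), per_position = per)
}

#' Aggregate read calls into a dyad class count table
#'
#' @param read_calls_list List of `read_calls`.
#' @param line Cell line name.
#' @param amplicon Amplicon name.
#' @return An object of class `dyad_count_table`: named integer counts over
#'   [observed_classes()] plus attributes `line`, `amplicon` and
#'   `analyzable` (total excluding mutated/unresolved dyads).
#' @export
dyad_count_table <- function(read_calls_list, line = "sample",
                             amplicon = "amplicon") {
  cls <- unlist(lapply(read_calls_list, `[[`, "dyads"))
  counts <- vapply(observed_classes(), function(k) sum(cls == k), integer(1))
  as_dyad_count_table(counts, line = line, amplicon = amplicon)
}

#' @rdname dyad_count_table
#' @param counts Named counts over (a subset of) [observed_classes()].
#' @export
as_dyad_count_table <- function(counts, line = "sample",
                                amplicon = "amplicon") {
  full <- stats::setNames(integer(length(observed_classes())),
                          observed_classes())
  full[names(counts)] <- as.integer(round(counts))
  if (any(full < 0)) stop("negative counts", call. = FALSE)
  structure(full, line = line, amplicon = amplicon,
            analyzable = sum(full[analyzable_classes()]),
            class = "dyad_count_table")
}

#' Write a textual pattern map of dyad classes
#'
#' One row per read, one column per dyad position; cell codes `U`, `HU`,
#' `HL`, `M`, `X` (mutated), `.` (unresolved) — a plain-text equivalent of a
#' double-stranded methylation heatmap.
#'
#' @param read_calls_list List of `read_calls`.
#' @param file Optional output path.
#' @return The pattern data.frame (invisibly when written).
#' @export
pattern_map <- function(read_calls_list, file = NULL) {
  if (!length(read_calls_list)) stop("no reads", call. = FALSE)
  posns <- sort(unique(unlist(lapply(read_calls_list,
                                     function(x) names(x$dyads)))))
  m <- do.call(rbind, lapply(read_calls_list, function(x) {
    out <- stats::setNames(rep(".", length(posns)), posns)
    out[names(x$dyads)] <- CLASS_CODES[x$dyads]
    out
  }))
  out <- data.frame(read_id = vapply(read_calls_list, `[[`, "", "read_id"),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("read_id", paste0("dyad_", posns))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
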