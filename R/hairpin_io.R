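#' Locate the hairpin linker in a read and split it into arms
#'
#' Scans the read and its reverse complement for the best occurrence of the
#' bisulfite-converted linker. At the linker's marked (unmethylated) C
#' offsets the read may carry C (conversion failure) or T (converted);
#' everywhere else the match must be exact. The read is split at the best
#' hit: the segment 5' of the linker is the upper-strand arm, the segment 3'
#' of it is the lower-strand arm (the lower strand read 5'-3', i.e. the
#' reverse complement of the reference orientation).
#'
#' @param read_seq Read sequence (character scalar).
#' @param ref An `amplicon_reference` (supplies the linker), or a list with
#'   `linker_seq` and `linker_marked`.
#' @param max_mismatches Maximum tolerated mismatches outside the C/T
#'   allowance (default 2).
#' @return List with `status` (`"ok"`, `"linker_not_found"` or
#'   `"ambiguous_linker"`), `upper_arm`, `lower_arm`, `linker_segment`,
#'   `orientation` (`"forward"` if the linker was found in the read as given,
#'   `"reverse"` if in its reverse complement), and `mismatches`.
#' @export
locate_linker <- function(read_seq, ref, max_mismatches = 2L) {
  linker <- toupper(ref$linker_seq)
  L <- nchar(linker)
  marked <- seq_len(L) %in% ref$linker_marked
  read_seq <- toupper(read_seq)
  if (nchar(read_seq) <= L)
    stop("read shorter than the linker", call. = FALSE)

  fwd <- .cpp_linker_scan(read_seq, linker, marked)
  rc_seq <- .revcomp(read_seq)
  rev <- .cpp_linker_scan(rc_seq, linker, marked)

  fail <- function(status) {
    list(status = status, upper_arm = NULL, lower_arm = NULL,
         linker_segment = NULL, orientation = NA_character_,
         mismatches = NA_integer_)
  }
  best_mm <- min(fwd[2], rev[2])
  if (best_mm > max_mismatches) return(fail("linker_not_found"))
  n_best <- sum(fwd[3][fwd[2] == best_mm], rev[3][rev[2] == best_mm])
  if (n_best > 1L) return(fail("ambiguous_linker"))

  if (fwd[2] <= rev[2]) {
    oriented <- read_seq; hit <- fwd; orientation <- "forward"
  } else {
    oriented <- rc_seq; hit <- rev; orientation <- "reverse"
  }
  s <- hit[1]
  list(status = "ok",
       upper_arm = substr(oriented, 1L, s - 1L),
       lower_arm = substr(oriented, s + L, nchar(oriented)),
       linker_segment = substr(oriented, s, s + L - 1L),
       orientation = orientation,
       mismatches = hit[2])
}

#' Align one arm of a hairpin read to its strand-local reference
#'
#' Global affine-gap alignment with bisulfite-aware scoring: a reference C
#' may read as C (methylated) or T (converted) at no penalty; all other
#' substitutions are penalized. For the lower strand the reference is the
#' reverse complement of the amplicon and calls are mapped back to
#' upper-strand coordinates, so each strand reports its own cytosines as
#' C/T in its own reading direction.
#'
#' @param arm_seq Arm sequence (strand-local, 5'-3').
#' @param ref An `amplicon_reference`.
#' @param strand `"upper"` or `"lower"`.
#' @param scores Named numeric vector `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (defaults +1, -2, -4, -1).
#' @return List with `calls` (character vector of length `nchar(upper_seq)`,
#'   entries in A/C/G/T/`-`, indexed by upper-strand position) and `identity`
#'   (fraction of matching non-C strand-local reference positions; C/T at
#'   reference Cs does not count against identity).
#' @export
align_arm <- function(arm_seq, ref, strand = c("upper", "lower"),
                      scores = c(match = 1, mismatch = -2,
                                 gap_open = -4, gap_extend = -1)) {
  strand <- match.arg(strand)
  arm_seq <- toupper(arm_seq)
  if (!nchar(arm_seq)) stop("empty arm", call. = FALSE)
  local_ref <- if (strand == "upper") ref$upper_seq else .revcomp(ref$upper_seq)

  aln <- .cpp_bisulfite_align(local_ref, arm_seq,
                              scores[["match"]], scores[["mismatch"]],
                              scores[["gap_open"]], scores[["gap_extend"]])
  ra <- .chars(aln$ref)
  qa <- .chars(aln$read)
  keep <- ra != "-"                      # drop read insertions
  ref_b <- ra[keep]
  call_b <- qa[keep]

  non_c <- ref_b != "C"
  identity <- if (any(non_c)) mean(call_b[non_c] == ref_b[non_c]) else 1

  n <- nchar(ref$upper_seq)
  calls <- call_b
  if (strand == "lower") calls <- rev(calls)   # back to upper coordinates
  names(calls) <- as.character(seq_len(n))
  list(calls = calls, identity = identity, score = aln$score)
}

#' Extract a full per-read profile from a raw hairpin read
#'
#' Composes [locate_linker()] and [align_arm()] on both arms, computes the
#' per-molecule bisulfite conversion rate from the linker's marked Cs
#' (`#T / (#C + #T)`), and counts how many CpG dyads have all four
#' informative bases called. Processing a read and its reverse complement
#' yields the same profile.
#'
#' @param read_seq Raw read sequence.
#' @param ref An `amplicon_reference`.
#' @param read_id Identifier carried through to outputs.
#' @param max_mismatches Forwarded to [locate_linker()].
#' @param scores Forwarded to [align_arm()].
#' @return An object of class `read_profile`: `read_id`, `upper_calls`,
#'   `lower_calls` (position-named base vectors in strand-local reading),
#'   `linker_calls`, `conversion_rate`, `identity_upper`, `identity_lower`,
#'   `n_covered_dyads`, `orientation`, `pass_filter` (set by
#'   [filter_reads()]; `FALSE` here only on rejection), `reject_reason`.
#' @export
extract_read_profile <- function(read_seq, ref, read_id = "read",
                                 max_mismatches = 2L,
                                 scores = c(match = 1, mismatch = -2,
                                            gap_open = -4, gap_extend = -1)) {
  out <- structure(
    list(read_id = read_id, upper_calls = NULL, lower_calls = NULL,
         linker_calls = NULL, conversion_rate = NA_real_,
         identity_upper = NA_real_, identity_lower = NA_real_,
         n_covered_dyads = 0L, orientation = NA_character_,
         pass_filter = FALSE, reject_reason = NA_character_),
    class = "read_profile")

  lk <- locate_linker(read_seq, ref, max_mismatches)
  if (lk$status != "ok") {
    out$reject_reason <- lk$status
    return(out)
  }
  if (!nchar(lk$upper_arm) || !nchar(lk$lower_arm)) {
    out$reject_reason <- "empty_arm"
    return(out)
  }
  up <- align_arm(lk$upper_arm, ref, "upper", scores)
  lo <- align_arm(lk$lower_arm, ref, "lower", scores)

  lb <- .chars(lk$linker_segment)[ref$linker_marked]
  n_ct <- sum(lb %in% c("C", "T"))
  conv <- if (n_ct) sum(lb == "T") / n_ct else NA_real_

  covered <- vapply(ref$dyad_pos, function(i) {
    all(c(up$calls[c(i, i + 1L)], lo$calls[c(i, i + 1L)]) %in%
          c("A", "C", "G", "T"))
  }, logical(1))

  out$upper_calls <- up$calls
  out$lower_calls <- lo$calls
  out$linker_calls <- lb
  out$conversion_rate <- conv
  out$identity_upper <- up$identity
  out$identity_lower <- lo$identity
  out$n_covered_dyads <- sum(covered)
  out$orientation <- lk$orientation
  out$pass_filter <- TRUE
  out
}

#' Quality-filter a set of read profiles
#'
#' Deterministically partitions profiles into kept and rejected sets.
#' Rejection reasons, in order of precedence: the extraction failure carried
#' by the profile (linker not found / ambiguous), `low_identity` (either
#' arm), `low_conversion`, `few_dyads`.
#'
#' @param profiles List of `read_profile` objects.
#' @param min_conversion Minimum per-molecule linker conversion rate
#'   (default 0.90).
#' @param min_identity Minimum alignment identity per arm (default 0.80).
#' @param min_covered_dyads Minimum fully-called CpG dyads (default 3; reads
#'   cover of the order of 3 to 12 dyads).
#' @return List with `kept` (profiles, `pass_filter = TRUE`), `rejected`
#'   (profiles with `reject_reason` set) and `reasons` (a named count table).
#' @export
filter_reads <- function(profiles, min_conversion = 0.90,
                         min_identity = 0.80, min_covered_dyads = 3L) {
  .check_prob(c(min_conversion, min_identity), "filter thresholds")
  reason <- vapply(profiles, function(p) {
    if (!is.na(p$reject_reason)) return(p$reject_reason)
    if (is.na(p$identity_upper) || p$identity_upper < min_identity ||
        p$identity_lower < min_identity) return("low_identity")
    if (is.na(p$conversion_rate) || p$conversion_rate < min_conversion)
      return("low_conversion")
    if (p$n_covered_dyads < min_covered_dyads) return("few_dyads")
    ""
  }, character(1))
  kept <- profiles[reason == ""]
  rejected <- mapply(function(p, r) { p$pass_filter <- FALSE
                                      p$reject_reason <- r; p },
                     profiles[reason != ""], reason[reason != ""],
                     SIMPLIFY = FALSE)
  list(kept = kept, rejected = rejected,
       reasons = table(reason[reason != ""]))
}

#' Read hairpin reads from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; the format is taken
#' from the file extension (`.fq`/`.fastq`, optionally `.gz`). FASTQ base
#' qualities are parsed by Biostrings but deliberately ignored downstream.
#'
#' @param path Input file.
#' @return Named character vector of read sequences.
#' @export
read_hairpin_reads <- function(path) {
  fastq <- grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)
  x <- Biostrings::readDNAStringSet(path, format = if (fastq) "fastq" else "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Run profile extraction over many reads and tabulate results
#'
#' @param reads Named character vector of read sequences (names become read
#'   ids), e.g. from [read_hairpin_reads()].
#' @param ref An `amplicon_reference`.
#' @param ... Forwarded to [extract_read_profile()].
#' @return List of `read_profile` objects.
#' @export
extract_profiles <- function(reads, ref, ...) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  mapply(extract_read_profile, reads, ids,
         MoreArgs = list(ref = ref, ...), SIMPLIFY = FALSE,
         USE.NAMES = FALSE)
}

#' Write per-read profile summaries as TSV
#'
#' One row per read: id, per-dyad class string (codes U/HU/HL/M/X/`.`),
#' conversion rate, per-arm identities, pass flag and rejection reason.
#'
#' @param profiles List of `read_profile`s.
#' @param ref The reference used to call dyad classes for the summary string.
#' @param file Optional output path.
#' @return The summary data.frame (invisibly when written to `file`).
#' @export
profile_table <- function(profiles, ref, file = NULL) {
  rows <- lapply(profiles, function(p) {
    classes <- if (isTRUE(p$pass_filter)) {
      rc <- call_read(p, ref)
      paste(CLASS_CODES[rc$dyads], collapse = ",")
    } else ""
    data.frame(read_id = p$read_id, dyad_classes = classes,
               conversion_rate = p$conversion_rate,
               identity_upper = p$identity_upper,
               identity_lower = p$identity_lower,
               n_covered_dyads = p$n_covered_dyads,
               pass_filter = p$pass_filter,
               reject_reason = ifelse(is.na(p$reject_reason), "",
                                      p$reject_reason),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
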