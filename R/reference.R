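#' Build an amplicon reference with CpG-dyad and non-CpG cytosine registries
#'
#' Enumerates, on the given ("upper") strand and its complement ("lower"
#' strand), every CpG dyad and every cytosine outside CpG context, excluding
#' primer-masked intervals. Coordinates are 1-based positions on the upper
#' strand; a dyad is indexed by the position of its upper-strand C, so its
#' lower-strand C sits at position `i + 1`. Lower-strand cytosines appear at
#' upper-strand G positions; their dinucleotide context is read 5'-3' along
#' the lower strand, i.e. towards decreasing upper-strand coordinates.
#'
#' @param seq Amplicon sequence (upper strand, 5'-3', A/C/G/T only), or a
#'   length-1 [Biostrings::DNAStringSet] as returned by
#'   [Biostrings::readDNAStringSet()].
#' @param name Amplicon identifier; defaults to the FASTA record name.
#' @param linker_seq Hairpin linker sequence (as ligated, unconverted).
#' @param linker_marked Integer offsets (1-based within the linker) of its
#'   unmethylated cytosines; between 5 and 7 must be marked, and each must be
#'   a C. These positions monitor bisulfite conversion per molecule.
#' @param primer_masks Optional two-column matrix or data.frame of 1-based
#'   inclusive `[start, end]` intervals excluded from all calling.
#' @return An object of class `amplicon_reference`: a list with `name`,
#'   `upper_seq`, `dyad_pos` (integer positions of upper-strand Cs of CpGs),
#'   `noncpg` (data.frame `pos`, `strand` in `upper`/`lower`, `context` in
#'   `CpA`/`CpT`/`CpC`), `linker_seq`, `linker_marked`, `primer_masks`.
#' @examples
#' ref <- build_reference("ACGT", name = "tiny")
#' ref$dyad_pos  # the single CpG, indexed by its upper-strand C
#' @export
build_reference <- function(seq, name = NULL,
                            linker_seq = default_linker()$seq,
                            linker_marked = default_linker()$marked,
                            primer_masks = NULL) {
  if (inherits(seq, "DNAStringSet")) {
    if (is.null(name)) name <- names(seq)[1]
    seq <- as.character(seq[[1]])
  }
  seq <- toupper(seq)
  .check_dna(seq, "reference sequence")
  if (is.null(name)) name <- "amplicon"
  n <- nchar(seq)

  masks <- .normalize_masks(primer_masks, n)
  masked <- rep(FALSE, n)
  if (nrow(masks)) {
    for (k in seq_len(nrow(masks))) masked[masks$start[k]:masks$end[k]] <- TRUE
  }

  b <- .chars(seq)
  is_dyad_c <- b[-n] == "C" & b[-1] == "G"          # upper C of a CpG at i
  dyad_pos <- which(is_dyad_c)
  dyad_pos <- dyad_pos[!masked[dyad_pos] & !masked[dyad_pos + 1L]]

  dyad_any <- rep(FALSE, n)                          # either C of any dyad
  dyad_any[dyad_pos] <- TRUE
  dyad_any[dyad_pos + 1L] <- TRUE

  # upper-strand non-CpG cytosines (need a 3' neighbour for context)
  up <- which(b == "C" & !dyad_any & !masked)
  up <- up[up < n]
  up <- up[!masked[up + 1L]]
  up_ctx <- paste0("Cp", b[up + 1L], recycle0 = TRUE)

  # lower-strand cytosines sit under upper Gs; next base 5'-3' on the lower
  # strand is the complement of the upper base at i-1
  lo <- which(b == "G" & !dyad_any & !masked)
  lo <- lo[lo > 1L]
  lo <- lo[!masked[lo - 1L]]
  lo_ctx <- paste0("Cp", .complement_chr(b[lo - 1L]), recycle0 = TRUE)

  noncpg <- data.frame(
    pos = c(up, lo),
    strand = rep(c("upper", "lower"), c(length(up), length(lo))),
    context = c(up_ctx, lo_ctx),
    stringsAsFactors = FALSE
  )
  noncpg <- noncpg[noncpg$context %in% c("CpA", "CpT", "CpC"), , drop = FALSE]
  noncpg <- noncpg[order(noncpg$pos, noncpg$strand), , drop = FALSE]
  rownames(noncpg) <- NULL

  .check_linker(linker_seq, linker_marked)

  structure(
    list(name = name, upper_seq = seq, dyad_pos = as.integer(dyad_pos),
         noncpg = noncpg, linker_seq = toupper(linker_seq),
         linker_marked = as.integer(linker_marked), primer_masks = masks),
    class = "amplicon_reference"
  )
}

.normalize_masks <- function(primer_masks, n) {
  if (is.null(primer_masks) || (is.data.frame(primer_masks) && !nrow(primer_masks)))
    return(data.frame(start = integer(), end = integer()))
  m <- as.data.frame(primer_masks)
  names(m)[1:2] <- c("start", "end")
  m$start <- as.integer(m$start); m$end <- as.integer(m$end)
  if (any(m$start < 1L | m$end > n | m$start > m$end))
    stop("primer mask outside the reference or inverted", call. = FALSE)
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1] <= m$end[-nrow(m)]))
    stop("overlapping primer masks", call. = FALSE)
  rownames(m) <- NULL
  m
}

.check_linker <- function(linker_seq, marked) {
  .check_dna(toupper(linker_seq), "linker sequence")
  marked <- as.integer(marked)
  if (length(marked) < 5L || length(marked) > 7L)
    stop("linker must have between 5 and 7 marked unmethylated Cs",
         call. = FALSE)
  lb <- .chars(toupper(linker_seq))
  if (any(marked < 1L | marked > length(lb)) || any(lb[marked] != "C"))
    stop("marked linker offsets must be C positions within the linker",
         call. = FALSE)
  invisible(TRUE)
}

#' Default hairpin linker
#'
#' A 20 nt synthetic hairpin linker with exactly six cytosines, all
#' unmethylated and marked for per-molecule conversion monitoring (hairpin
#' linkers carry 5 to 7 such Cs).
#' @return List with `seq` and integer `marked` offsets.
#' @export
default_linker <- function() {
  seq <- "GGACTTCGATCAGCTACGTC"
  list(seq = seq, marked = which(.chars(seq) == "C"))
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference '%s': %d bp, %d CpG dyads, %d non-CpG Cs (%d masked intervals)\n",
              x$name, nchar(x$upper_seq), length(x$dyad_pos),
              nrow(x$noncpg), nrow(x$primer_masks)))
  invisible(x)
}

#' Dump the position registry of a reference as a TSV-ready data.frame
#'
#' One row per registered position: CpG dyads (kind `dyad`, strand `both`)
#' and non-CpG cytosines with strand and context. Written with
#' [utils::write.table()] when `file` is given.
#'
#' @param ref An [build_reference()] object.
#' @param file Optional output path.
#' @return Invisibly (or visibly when `file` is `NULL`) the registry
#'   data.frame with columns `name`, `pos`, `kind`, `strand`, `context`.
#' @export
reference_registry <- function(ref, file = NULL) {
  stopifnot(inherits(ref, "amplicon_reference"))
  reg <- rbind(
    data.frame(name = ref$name, pos = ref$dyad_pos, kind = "dyad",
               strand = "both", context = "CpG", stringsAsFactors = FALSE),
    data.frame(name = ref$name, pos = ref$noncpg$pos, kind = "noncpg",
               strand = ref$noncpg$strand, context = ref$noncpg$context,
               stringsAsFactors = FALSE)
  )
  reg <- reg[order(reg$pos), , drop = FALSE]
  rownames(reg) <- NULL
  if (!is.null(file)) {
    utils::write.table(reg, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(reg))
  }
  reg
}

#' Synthetic major-satellite-like demonstration amplicon
#'
#' A fixed 234 bp AT-rich synthetic sequence (not a genomic sequence) in the
#' style of a mouse major-satellite hairpin amplicon: 8 CpG dyads and a
#' spread of CpA/CpT/CpC cytosines on both strands. Used by examples, tests
#' and the simulator as a self-contained stand-in reference.
#'
#' @param primer_masks Optional masks forwarded to [build_reference()].
#' @return An `amplicon_reference`.
#' @export
synthetic_msat_reference <- function(primer_masks = NULL) {
  seq <- paste0(
    "GGAAAATTTAGAAATGTCCACTGTAGGACGTGGAATATGGCAAGAAAACTGAAAATCACG",
    "GAAAATGAGAAATACACACTTTAGGACGTGAAATATGGCGAGAAAACTGAAAATCATGGA",
    "AAATGAGAAACGTGGAAAAGGACCTGAAATATGGCGAGGAAAACTGAAAAAGGTGGAAAA",
    "TTTAGAAATGTCCACTGTAGGACGGTGGAATATGGCAAGAAAACTGAAAACGTG"
  )
  build_reference(seq, name = "mSat_synthetic", primer_masks = primer_masks)
}
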