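#' @useDynLib hairpinMeth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Dyad states and observed dyad classes
#'
#' A CpG dyad (the palindromic pair of cytosines at a CpG site) carries one of
#' four true methylation states: `U` (both strands unmethylated), `HU` (upper
#' strand methylated only), `HL` (lower strand methylated only), `M` (both
#' methylated). A hairpin read reports one of seven observed classes: the four
#' analyzable classes `UNMETH`/`HEMI_UPPER`/`HEMI_LOWER`/`FULL`, the two
#' genomic-mutation classes `MUT_UPPER`/`MUT_LOWER` (CpG-to-TpG on one
#' strand), and the sink class `UNRESOLVED` (gaps or bases inconsistent with
#' any bisulfite outcome). Mutated and unresolved dyads are excluded from all
#' methylation statistics and model likelihoods.
#'
#' @format `dyad_states()` returns a character vector of length 4,
#'   `observed_classes()` one of length 7 (analyzable classes first).
#' @export
dyad_states <- function() c("U", "HU", "HL", "M")

#' @rdname dyad_states
#' @export
observed_classes <- function() {
  c("UNMETH", "HEMI_UPPER", "HEMI_LOWER", "FULL",
    "MUT_UPPER", "MUT_LOWER", "UNRESOLVED")
}

#' @rdname dyad_states
#' @export
analyzable_classes <- function() observed_classes()[1:4]

# enzymes modelled throughout
DNMT_ENZYMES <- c("Dnmt1", "Dnmt3a", "Dnmt3b")

# single-character codes used in pattern-map TSVs
CLASS_CODES <- c(UNMETH = "U", HEMI_UPPER = "HU", HEMI_LOWER = "HL",
                 FULL = "M", MUT_UPPER = "X", MUT_LOWER = "X",
                 UNRESOLVED = ".")
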