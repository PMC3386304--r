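# internal sequence helpers; sequences are plain upper-case character scalars

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

.complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp <- function(s) .collapse(rev(.chars(.complement_chr(s))))

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(seq)
}

.check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(what, " must be in [0, 1]", call. = FALSE)
  invisible(p)
}

# run `expr` under a local RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
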