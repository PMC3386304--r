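#' Read a run configuration (YAML)
#'
#' Key-value configuration for the calling pipeline. Recognized keys (all
#' optional, defaults in parentheses): `linker.seq` and `linker.marked`
#' (the built-in [default_linker()]), `primer_masks` (none; list of
#' `[start, end]` pairs), `max_mismatches` (2), `min_conversion` (0.90),
#' `min_identity` (0.80), `min_covered_dyads` (3), `scores` with `match`
#' (1), `mismatch` (-2), `gap_open` (-4), `gap_extend` (-1).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  lk <- default_linker()
  defaults <- list(
    linker = list(seq = lk$seq, marked = lk$marked),
    primer_masks = NULL,
    max_mismatches = 2L,
    min_conversion = 0.90,
    min_identity = 0.80,
    min_covered_dyads = 3L,
    scores = list(match = 1, mismatch = -2, gap_open = -4, gap_extend = -1)
  )
  merge <- function(def, got) {
    for (k in names(got)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(got[[k]]))
        merge(def[[k]], got[[k]]) else got[[k]]
    }
    def
  }
  out <- merge(defaults, cfg)
  if (!is.null(out$primer_masks))
    out$primer_masks <- do.call(rbind, lapply(out$primer_masks, unlist))
  out
}

#' Read cell-line regimes from a YAML config
#'
#' Expects a top-level `regimes` list; each entry has `line_name`,
#' `active_enzymes`, `generations`, `pi0` (length-4 over `U, HU, HL, M`)
#' and optionally `passage`.
#'
#' @param path YAML file.
#' @return Named list of [cell_line_regime()]s.
#' @export
read_regimes_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regimes)) stop("config has no 'regimes' key", call. = FALSE)
  out <- lapply(cfg$regimes, function(r) {
    cell_line_regime(r$line_name, unlist(r$active_enzymes), r$generations,
                     unlist(r$pi0), passage = r$passage)
  })
  names(out) <- vapply(out, `[[`, "", "line_name")
  out
}

#' Write and read dyad-class count tables as TSV
#'
#' Long format: columns `line`, `amplicon`, `class`, `count`.
#'
#' @param count_tables A `dyad_count_table` or list of them.
#' @param file Output path.
#' @export
write_count_tables <- function(count_tables, file) {
  if (inherits(count_tables, "dyad_count_table"))
    count_tables <- list(count_tables)
  rows <- lapply(count_tables, function(ct) {
    data.frame(line = attr(ct, "line"), amplicon = attr(ct, "amplicon"),
               class = names(ct), count = as.integer(ct),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_count_tables
#' @return `read_count_tables()`: named list of `dyad_count_table`s, one
#'   per (line, amplicon) pair found in the file.
#' @export
read_count_tables <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("line", "amplicon", "class", "count")
  if (!all(need %in% names(d)))
    stop("count TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(d$line, d$amplicon, drop = TRUE)
  out <- lapply(split(d, key), function(g) {
    as_dyad_count_table(stats::setNames(g$count, g$class),
                        line = g$line[1], amplicon = g$amplicon[1])
  })
  names(out) <- vapply(out, attr, "", "line")
  out
}

#' Serialize a fit as JSON
#'
#' @param fit A `dnmt_fit`.
#' @param file Output path.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "dnmt_fit"))
  out <- list(
    estimates = as.list(fit$estimates),
    sd = as.list(fit$sd),
    flags = as.list(fit$flags),
    loglik = fit$loglik,
    convergence = fit$convergence,
    mode = fit$mode, c_fail = fit$c_fail, c_over = fit$c_over,
    free_enzymes = fit$free_enzymes,
    never_active = fit$never_active,
    predicted = lapply(fit$predicted, function(d) as.list(d))
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
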