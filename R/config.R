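#' Run configuration for the scaffolder
#'
#' Builds the configuration list used throughout the pipeline. All values can
#' be overridden either by arguments or by a plain `key = value` text file.
#' Defaults are the method's standard settings: contigs shorter than
#' `max(500, 2 * paired-end insert)` are left unscaffolded, edges with fewer
#' than 5 supporting pairs are discarded, repeat classification uses a 1.5x
#' coverage factor, edge concordance windows are +/- 6 standard deviations,
#' the exact search explores at most one million states per subgraph before
#' escalating the support threshold by 1, and staged multi-library
#' scaffolding groups libraries at 1 kbp / 10 kbp insert-size boundaries.
#'
#' @param path optional path to a `key = value` (or `key=value`) config file;
#'   `#` starts a comment. Unknown keys are an error.
#' @param ... named overrides applied after the file (same key set).
#' @return a named list of class `"scafex_config"`.
#' @examples
#' cfg <- scafex_config(edge_support = 1)   # long-read mode default
#' cfg$edge_support
#' @export
scafex_config <- function(path = NULL, ...) {
  cfg <- list(
    repeat_factor     = 1.5,    # coverage multiple above which a contig is a repeat
    edge_support      = 5,      # minimum supporting pairs per scaffold edge
    sd_multiplier     = 6,      # concordance window half-width, in edge SDs
    state_cap         = 1e6,    # max explored search states per subgraph
    support_step      = 1,      # support-threshold increment of the hybrid fallback
    stage_boundaries  = c(1000, 10000),  # staged library grouping (bp, upper-inclusive)
    min_contig_length = 500,    # floor of the contig-size filter
    pe_insert         = 0,      # paired-end insert used in max(500, 2*pe) filter
    sigma_floor       = 1,      # bp; keeps windows finite and positive
    gap_min           = -500,   # bp; allows modest contig overlap
    gap_max           = NA_real_, # default: max library span bound L
    max_repeat_copies = 2,      # parsimony cap on instances per repeat contig
    overlap_slack     = 500,    # bp of headroom in reachability tests (= |gap_min|)
    lookup_bucket     = 500,    # bp; contig-length-sum bucketing of lookup tables
    use_support_weights = TRUE, # weight gap-sizing constraints by pair support
    memo              = TRUE,   # memoize the exact search
    staged            = FALSE   # staged multi-library scaffolding
  )
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      cfg <- .cfg_set(cfg, key, val)
    }
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("config overrides must be named")
    for (key in names(dots)) cfg <- .cfg_set(cfg, key, dots[[key]])
  }
  structure(cfg, class = "scafex_config")
}

.cfg_set <- function(cfg, key, val) {
  if (!key %in% names(cfg))
    stop("unknown configuration key: '", key, "'")
  old <- cfg[[key]]
  if (is.character(val)) {
    if (is.logical(old)) {
      val <- as.logical(val)
    } else if (is.numeric(old)) {
      val <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  cfg[[key]] <- val
  cfg
}

#' @export
print.scafex_config <- function(x, ...) {
  cat("scaffolder configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-19s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
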