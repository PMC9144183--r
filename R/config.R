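# Pipeline configuration: defaults, YAML parsing, validation, and the
# stage-count summary writer.

#' Default pipeline configuration
#'
#' All input paths default to `NULL` (the pipeline errors, naming the stage,
#' when a needed input is absent); thresholds default to the package-wide
#' values: 2 kb promoter window, islands starting at least 200 bp upstream of
#' the TSS, CGI criteria GC% > 50 / obs-exp > 0.6 / length > 200, q < 0.05,
#' `|delta beta| >= 0.1`, `|log2fc| >= 1`.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    genome = NULL, annotation = NULL, annotation_format = "auto",
    deg = NULL,
    beta = NULL, meth_samples = NULL, methylation_calls = NULL,
    tpm = NULL, expr_samples = NULL, expression_calls = NULL,
    cgi_presence = NULL, gene_sets = NULL,
    upstream = 2000L, downstream = 0L, min_upstream_start = 200L,
    min_gc = 50, min_oe = 0.6, min_length = 200L, window = 200L, step = 1L,
    q_threshold = 0.05, delta_beta_threshold = 0.1, lfc_threshold = 1,
    pseudocount = 1, seed = 1L, out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults for absent fields, rejects unknown keys (listing them), and
#' checks threshold ranges.
#'
#' @param config Partial configuration list.
#' @return The fully resolved configuration.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  with(cfg, {
    if (!(min_gc > 0 && min_gc < 100)) stop("min_gc must lie in (0, 100)")
    if (min_oe <= 0) stop("min_oe must be > 0")
    if (!(min_length >= window && window >= 1L)) {
      stop("need min_length >= window >= 1")
    }
    if (step < 1L) stop("step must be >= 1")
    if (upstream < 1L || downstream < 0L) stop("invalid promoter window")
    if (min_upstream_start < 0L || min_upstream_start > upstream) {
      stop("min_upstream_start must lie in [0, upstream]")
    }
    if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must lie in (0, 1]")
    if (delta_beta_threshold < 0 || delta_beta_threshold > 1) {
      stop("delta_beta_threshold must lie in [0, 1]")
    }
    if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
    if (pseudocount <= 0) stop("pseudocount must be > 0")
  })
  cfg
}

#' Parse a YAML pipeline configuration
#'
#' @param path YAML file; keys as in [default_config()].
#' @return Resolved, validated configuration list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  validate_config(cfg)
}

# Summary text: stage counts plus a one-line flow and the parameter echo.
format_summary <- function(summary, config = NULL) {
  lines <- c(
    "target filtration summary",
    sprintf("input DEGs:            %d", summary$n_deg),
    sprintf("with promoter CGI:     %d", summary$n_cgi),
    sprintf("oncogene-like:         %d", summary$n_oncogene_like),
    sprintf("tumor-suppressor-like: %d", summary$n_tumor_suppressor_like),
    sprintf("unclassified:          %d", summary$n_unclassified),
    sprintf("flow: %d -> %d -> %d + %d", summary$n_deg, summary$n_cgi,
            summary$n_oncogene_like, summary$n_tumor_suppressor_like)
  )
  if (!is.null(config)) {
    lines <- c(lines, "", "parameters:", sprintf(
      "  upstream=%d downstream=%d min_upstream_start=%d", config$upstream,
      config$downstream, config$min_upstream_start
    ), sprintf(
      "  min_gc=%g min_oe=%g min_length=%d window=%d step=%d", config$min_gc,
      config$min_oe, config$min_length, config$window, config$step
    ), sprintf(
      "  q=%g delta_beta=%g lfc=%g pseudocount=%g seed=%d", config$q_threshold,
      config$delta_beta_threshold, config$lfc_threshold, config$pseudocount,
      config$seed
    ))
  }
  lines
}

#' Write the stage-count summary of a target report
#'
#' @param report Tibble from [build_target_report()], or the summary list from
#'   [summarize_targets()].
#' @param path Optional file to write the text summary to.
#' @param config Optional resolved configuration, echoed below the counts.
#' @return The summary lines, invisibly when `path` is given.
#' @export
write_summary <- function(report, path = NULL, config = NULL) {
  summary <- if (is.data.frame(report)) summarize_targets(report) else report
  lines <- format_summary(summary, config)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
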