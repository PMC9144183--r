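# Core filtration pipeline: DEG list -> promoter-CGI subset -> direction
# concordance classification into oncogene-like and tumor-suppressor-like
# candidates.

#' Keep the DEGs whose promoter carries a CpG island
#'
#' DEG ids missing from the presence map are logged and treated as CGI-free.
#' Input order is preserved.
#'
#' @param deg_gene_ids Character vector of DEG gene ids.
#' @param cgi_presence Named logical vector, `TRUE` when the gene's promoter
#'   carries a qualifying island.
#' @return The subset of `deg_gene_ids` with a promoter island, in order.
#' @export
filter_cgi_genes <- function(deg_gene_ids, cgi_presence) {
  stopifnot(is.character(deg_gene_ids), is.logical(cgi_presence))
  missing <- setdiff(deg_gene_ids, names(cgi_presence))
  if (length(missing)) {
    message(length(missing), " DEG id(s) absent from CGI presence map, ",
            "treated as CGI-free: ", paste(missing, collapse = ", "))
  }
  has <- cgi_presence[deg_gene_ids]
  has[is.na(has)] <- FALSE
  deg_gene_ids[has]
}

#' Classify a gene by expression-methylation concordance
#'
#' Concordant activation (`up` + `hypomethylated`) is oncogene-like;
#' concordant silencing (`down` + `hypermethylated`) is
#' tumor-suppressor-like; every other direction pair is unclassified.
#' Vectorized over both arguments.
#'
#' @param expression_direction `up`, `down` or `none`.
#' @param methylation_direction `hypomethylated`, `hypermethylated` or `none`.
#' @return Character vector over
#'   `{oncogene-like, tumor-suppressor-like, unclassified}`.
#' @export
classify_target <- function(expression_direction, methylation_direction) {
  ok_e <- expression_direction %in% c("up", "down", "none")
  ok_m <- methylation_direction %in% c("hypomethylated", "hypermethylated", "none")
  if (!all(ok_e)) {
    stop("invalid expression direction: ",
         paste(unique(expression_direction[!ok_e]), collapse = ", "))
  }
  if (!all(ok_m)) {
    stop("invalid methylation direction: ",
         paste(unique(methylation_direction[!ok_m]), collapse = ", "))
  }
  dplyr::case_when(
    expression_direction == "up" & methylation_direction == "hypomethylated" ~
      "oncogene-like",
    expression_direction == "down" & methylation_direction == "hypermethylated" ~
      "tumor-suppressor-like",
    TRUE ~ "unclassified"
  )
}

#' Assemble the per-DEG target report
#'
#' One row per DEG in input order. Genes without a promoter island are carried
#' as unclassified (never dropped) so stage counts remain auditable; genes
#' missing from a call table get direction `none` and NA statistics.
#'
#' @param deg_gene_ids DEG gene ids, defining report order.
#' @param cgi_presence Named logical CGI presence map.
#' @param expression_calls Tibble from [call_expression()] (or a precomputed
#'   table with `gene_id`, `direction` and optionally `log2fc`, `q_value`).
#' @param methylation_calls Tibble from [call_methylation()] (or precomputed
#'   with `gene_id`, `direction` and optionally `delta_beta`, `q_value`).
#' @return Tibble with columns `gene_id`, `has_cgi`, `expr_dir`, `log2fc`,
#'   `q_expr`, `meth_dir`, `delta_beta`, `q_meth`, `target_class`.
#' @export
build_target_report <- function(deg_gene_ids, cgi_presence, expression_calls,
                                methylation_calls) {
  has <- cgi_presence[deg_gene_ids]
  has[is.na(has)] <- FALSE
  pick <- function(calls, col, default = NA_real_) {
    if (is.null(calls) || !col %in% names(calls)) {
      return(rep(default, length(deg_gene_ids)))
    }
    calls[[col]][match(deg_gene_ids, calls$gene_id)]
  }
  expr_dir <- pick(expression_calls, "direction", NA_character_)
  expr_dir[is.na(expr_dir)] <- "none"
  meth_dir <- pick(methylation_calls, "direction", NA_character_)
  meth_dir[is.na(meth_dir)] <- "none"
  cls <- classify_target(expr_dir, meth_dir)
  cls[!has] <- "unclassified"
  tibble::tibble(
    gene_id = deg_gene_ids,
    has_cgi = unname(has),
    expr_dir = expr_dir,
    log2fc = pick(expression_calls, "log2fc"),
    q_expr = pick(expression_calls, "q_value"),
    meth_dir = meth_dir,
    delta_beta = pick(methylation_calls, "delta_beta"),
    q_meth = pick(methylation_calls, "q_value"),
    target_class = cls
  )
}

#' Stage counts of a target report
#'
#' @param report Tibble from [build_target_report()].
#' @return Named list: `n_deg`, `n_cgi`, `n_oncogene_like`,
#'   `n_tumor_suppressor_like`, `n_unclassified`.
#' @export
summarize_targets <- function(report) {
  list(
    n_deg = nrow(report),
    n_cgi = sum(report$has_cgi),
    n_oncogene_like = sum(report$target_class == "oncogene-like"),
    n_tumor_suppressor_like = sum(report$target_class == "tumor-suppressor-like"),
    n_unclassified = sum(report$target_class == "unclassified")
  )
}

#' Run the full filtration pipeline from a configuration
#'
#' Executes promoter extraction, CpG-island scanning, differential methylation
#' and expression calls, CGI filtering, and concordance classification, then
#' writes the per-gene report, a stage-count summary, and the resolved
#' configuration into `out_dir` (when set). Any stage can instead be fed
#' precomputed tables (`cgi_presence`, `expression_calls`,
#' `methylation_calls` paths in the config).
#'
#' @param config List from [parse_config()] or [default_config()].
#' @return List with `report`, `summary`, `config` (resolved) and, when
#'   computed, `promoters`, `cgi`, `expression_calls`, `methylation_calls`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- list()

  deg <- if (is.null(config$deg)) {
    stop("pipeline stage 'deg': no DEG table configured")
  } else {
    read_deg_table(config$deg)
  }

  # CGI presence: precomputed map or genome + annotation scan
  if (!is.null(config$cgi_presence)) {
    pres_df <- readr::read_tsv(config$cgi_presence, show_col_types = FALSE,
                               progress = FALSE)
    if (!all(c("gene_id", "has_cgi") %in% names(pres_df))) {
      stop("pipeline stage 'cgi': presence table needs gene_id and has_cgi columns")
    }
    presence <- stats::setNames(as.logical(pres_df$has_cgi), pres_df$gene_id)
  } else if (!is.null(config$genome) && !is.null(config$annotation)) {
    genome <- read_genome_fasta(config$genome)
    genes <- read_gene_annotation(config$annotation,
                                  format = config$annotation_format,
                                  genome = genome)
    out$promoters <- extract_promoters(genes, genome,
                                       upstream = config$upstream,
                                       downstream = config$downstream)
    params <- cgi_params(min_gc = config$min_gc, min_oe = config$min_oe,
                         min_length = config$min_length,
                         window = config$window, step = config$step)
    out$cgi <- scan_promoter_cgi(out$promoters, params,
                                 min_upstream_start = config$min_upstream_start)
    presence <- stats::setNames(out$cgi$has_cgi, out$cgi$gene_id)
  } else {
    stop("pipeline stage 'cgi': need either cgi_presence or genome + annotation")
  }

  # Direction calls: precomputed tables or matrices + sample sheets
  read_calls <- function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("gene_id", "direction") %in% names(df))) {
      stop("precomputed call table needs gene_id and direction columns: ", path)
    }
    df
  }
  expr_calls <- if (!is.null(config$expression_calls)) {
    read_calls(config$expression_calls)
  } else if (!is.null(config$tpm) && !is.null(config$expr_samples)) {
    call_expression(read_matrix_table(config$tpm),
                    read_sample_sheet(config$expr_samples),
                    lfc_threshold = config$lfc_threshold,
                    q_threshold = config$q_threshold,
                    pseudocount = config$pseudocount)
  } else {
    stop("pipeline stage 'expression': need expression_calls or tpm + expr_samples")
  }
  meth_calls <- if (!is.null(config$methylation_calls)) {
    read_calls(config$methylation_calls)
  } else if (!is.null(config$beta) && !is.null(config$meth_samples)) {
    call_methylation(read_matrix_table(config$beta),
                     read_sample_sheet(config$meth_samples),
                     delta_threshold = config$delta_beta_threshold,
                     q_threshold = config$q_threshold)
  } else {
    stop("pipeline stage 'methylation': need methylation_calls or beta + meth_samples")
  }
  out$expression_calls <- expr_calls
  out$methylation_calls <- meth_calls

  report <- build_target_report(deg$gene_id, presence, expr_calls, meth_calls)
  out$report <- report
  out$summary <- summarize_targets(report)
  out$config <- config

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(report, file.path(config$out_dir, "target_report.tsv"))
    writeLines(format_summary(out$summary, config),
               file.path(config$out_dir, "summary.txt"))
    yaml::write_yaml(config[!vapply(config, is.null, logical(1L))],
                     file.path(config$out_dir, "config_resolved.yaml"))
  }
  out
}
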