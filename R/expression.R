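# Tumor-vs-normal differential expression calls on TPM matrices.

#' Log2 fold change of group mean TPM
#'
#' `log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))`. The
#' pseudocount guards against zero means; its influence vanishes for strongly
#' expressed genes.
#'
#' @param mean_tumor,mean_normal Non-negative group mean TPM values.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Log2 fold change (vectorized).
#' @export
log2_fold_change <- function(mean_tumor, mean_normal, pseudocount = 1) {
  if (any(mean_tumor < 0) || any(mean_normal < 0)) {
    stop("mean TPM values must be non-negative")
  }
  stopifnot(all(pseudocount > 0))
  log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))
}

#' Tumor-vs-normal differential expression calls
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on `log2(TPM + 1)` between
#' groups, Benjamini-Hochberg adjustment across genes, and a log2 fold change
#' of group mean TPM. A direction (`up` / `down`) is assigned only when
#' `q < q_threshold` and `|log2fc| >= lfc_threshold`; otherwise `none`.
#'
#' @param tpm Genes x samples matrix of non-negative TPM values, gene ids as
#'   row names.
#' @param group Per-sample labels, `tumor` or `normal`.
#' @param lfc_threshold Minimum absolute log2 fold change (default 1).
#' @param q_threshold FDR cutoff (default 0.05).
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return Tibble with `gene_id`, `mean_tpm_tumor`, `mean_tpm_normal`,
#'   `log2fc`, `p_value`, `q_value`, `direction`.
#' @export
call_expression <- function(tpm, group, lfc_threshold = 1, q_threshold = 0.05,
                            pseudocount = 1) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)),
            lfc_threshold >= 0, q_threshold > 0, q_threshold <= 1)
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene ids in TPM matrix")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  group <- match_groups(tpm, group)
  mt <- rowMeans(tpm[, group == "tumor", drop = FALSE])
  mn <- rowMeans(tpm[, group == "normal", drop = FALSE])
  lfc <- log2_fold_change(mt, mn, pseudocount)
  p <- row_rank_test(log2(tpm + 1), group)
  q <- bh_adjust(p)
  direction <- rep("none", nrow(tpm))
  sig <- q < q_threshold & abs(lfc) >= lfc_threshold
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"
  tibble::tibble(
    gene_id = rownames(tpm),
    mean_tpm_tumor = unname(mt),
    mean_tpm_normal = unname(mn),
    log2fc = unname(lfc),
    p_value = unname(p),
    q_value = unname(q),
    direction = direction
  )
}

#' Read a differentially-expressed-gene table
#'
#' Accepts the precomputed-DEG path for inputs where raw samples are
#' unavailable. Requires a `gene_id` column; `log2fc`, `p_value` and
#' `direction` are optional. When `direction` is absent but `log2fc` is
#' present, direction is derived from the sign of `log2fc`.
#'
#' @param path TSV (or CSV) file.
#' @return Tibble with `gene_id` and any of `log2fc`, `p_value`, `direction`.
#' @export
read_deg_table <- function(path) {
  stopifnot(file.exists(path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"gene_id" %in% names(df)) stop("DEG table needs a gene_id column: ", path)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in DEG table: ", path)
  if (!"direction" %in% names(df) && "log2fc" %in% names(df)) {
    df$direction <- dplyr::case_when(
      df$log2fc > 0 ~ "up",
      df$log2fc < 0 ~ "down",
      TRUE ~ "none"
    )
  }
  if ("direction" %in% names(df)) {
    bad <- setdiff(unique(df$direction), c("up", "down", "none"))
    if (length(bad)) stop("unknown DEG direction(s): ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(df)
}
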