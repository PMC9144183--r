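# Beta-value computation and tumor-vs-normal differential methylation calls.

#' Methylation beta value from allele intensities
#'
#' The beta value is the ratio of methylated-allele intensity to total
#' intensity, `m / (m + u + offset)`: 0 means unmethylated and 1 fully
#' methylated. Vectorized; inputs recycle as usual.
#'
#' @param m Methylated-allele intensity (>= 0).
#' @param u Unmethylated-allele intensity (>= 0).
#' @param offset Non-negative stabilizing offset added to the denominator
#'   (default 0; array-style pipelines often use 100).
#' @return Beta values in `[0, 1]`.
#' @export
beta_value <- function(m, u, offset = 0) {
  if (any(m < 0) || any(u < 0) || any(offset < 0)) {
    stop("intensities and offset must be non-negative")
  }
  denom <- m + u + offset
  if (any(denom == 0)) stop("all-zero denominator: m + u + offset must be > 0")
  m / denom
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input. Thin validation
#' wrapper around [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

# Two-sided Wilcoxon rank-sum p-value per row of a genes x samples matrix.
# Constant rows (identical values across both groups) get p = 1.
row_rank_test <- function(mat, group) {
  t_idx <- group == "tumor"
  n_idx <- group == "normal"
  if (sum(t_idx) < 2L || sum(n_idx) < 2L) {
    stop("need >= 2 samples per group (tumor: ", sum(t_idx),
         ", normal: ", sum(n_idx), ")")
  }
  apply(mat, 1L, function(x) {
    if (length(unique(x)) == 1L) return(1)
    p <- suppressWarnings(
      stats::wilcox.test(x[t_idx], x[n_idx], exact = FALSE)$p.value
    )
    if (is.na(p)) 1 else p
  })
}

#' Tumor-vs-normal differential methylation calls
#'
#' Per gene: group means, delta beta (tumor minus normal), a two-sided
#' Wilcoxon rank-sum test between groups and Benjamini-Hochberg adjustment
#' across genes. A direction is assigned only when `q < q_threshold` and
#' `|delta_beta| >= delta_threshold`; otherwise `none`.
#'
#' @param beta Genes x samples matrix of beta values in `[0, 1]`, gene ids as
#'   row names.
#' @param group Per-sample labels, `tumor` or `normal` (named vectors are
#'   aligned to the matrix columns).
#' @param delta_threshold Minimum absolute delta beta (default 0.1).
#' @param q_threshold FDR cutoff (default 0.05).
#' @return Tibble with `gene_id`, `mean_beta_tumor`, `mean_beta_normal`,
#'   `delta_beta`, `p_value`, `q_value`, `direction`
#'   (`hypomethylated` / `hypermethylated` / `none`).
#' @export
call_methylation <- function(beta, group, delta_threshold = 0.1,
                             q_threshold = 0.05) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)),
            delta_threshold >= 0, q_threshold > 0, q_threshold <= 1)
  if (anyDuplicated(rownames(beta))) stop("duplicate gene ids in beta matrix")
  if (any(beta < 0) || any(beta > 1)) stop("beta values must lie in [0, 1]")
  group <- match_groups(beta, group)
  mt <- rowMeans(beta[, group == "tumor", drop = FALSE])
  mn <- rowMeans(beta[, group == "normal", drop = FALSE])
  p <- row_rank_test(beta, group)
  q <- bh_adjust(p)
  db <- mt - mn
  direction <- rep("none", nrow(beta))
  sig <- q < q_threshold & abs(db) >= delta_threshold
  direction[sig & db < 0] <- "hypomethylated"
  direction[sig & db > 0] <- "hypermethylated"
  tibble::tibble(
    gene_id = rownames(beta),
    mean_beta_tumor = unname(mt),
    mean_beta_normal = unname(mn),
    delta_beta = unname(db),
    p_value = unname(p),
    q_value = unname(q),
    direction = direction
  )
}

#' Collapse probe-level betas to gene level
#'
#' Probes mapping to the same gene's promoter are summarized per sample by the
#' mean (or median) beta before differential testing.
#'
#' @param beta Probes x samples matrix, probe ids as row names.
#' @param probe_to_gene Named character vector mapping probe id to gene id.
#' @param method `"mean"` (default) or `"median"`.
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(beta, probe_to_gene, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  missing <- setdiff(rownames(beta), names(probe_to_gene))
  if (length(missing)) {
    stop("probe(s) without gene mapping: ", paste(missing, collapse = ", "))
  }
  genes <- probe_to_gene[rownames(beta)]
  fun <- if (method == "mean") mean else stats::median
  out <- do.call(rbind, lapply(split(seq_len(nrow(beta)), genes), function(i) {
    apply(beta[i, , drop = FALSE], 2L, fun)
  }))
  out[order(rownames(out)), , drop = FALSE]
}
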