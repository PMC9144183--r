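# Hypergeometric over-representation analysis against GMT gene sets.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the number of hits `X` when drawing `n` genes from a
#' universe of `N` containing `K` set members.
#'
#' @param k Observed hits (list genes inside the set).
#' @param K Set size within the universe.
#' @param n Gene-list size within the universe.
#' @param N Universe size.
#' @return The over-representation p-value, in `(0, 1]`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  sets <- fgsea::gmtPathways(path)
  if (!length(sets)) stop("no gene sets in ", path)
  sets
}

#' Over-representation analysis of a gene list
#'
#' Each set is intersected with the universe, the list's overlap is scored by
#' the upper-tail hypergeometric test, and q-values are Benjamini-Hochberg
#' adjusted across the reported sets. Sets with no overlap with the gene list
#' are omitted. Rows are sorted by p ascending, ties broken by set name.
#'
#' @param gene_list Character vector of gene ids.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe Optional universe of gene ids; defaults to the union of all
#'   set members.
#' @return Tibble with `set`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @export
enrich <- function(gene_list, sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  genes <- unique(intersect(as.character(gene_list), universe))
  if (!length(genes)) stop("gene list has no overlap with the universe")
  N <- length(universe)
  n <- length(genes)
  rows <- purrr::imap(sets, function(members, name) {
    set_u <- intersect(unique(members), universe)
    k <- length(intersect(genes, set_u))
    if (k == 0L) return(NULL)
    tibble::tibble(set = name, k = k, K = length(set_u), n = n, N = N,
                   p_value = hypergeom_test(k, length(set_u), n, N))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble::tibble(set = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p_value = double(),
                          q_value = double()))
  }
  res$q_value <- bh_adjust(res$p_value)
  dplyr::arrange(res, .data$p_value, .data$set)
}
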