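# CpG-island detection: sliding-window scan under Gardiner-Garden-type
# criteria (GC% > min_gc, observed/expected CpG > min_oe, length > min_length)
# with Takai-Jones-style merge of qualifying windows and per-region trimming.

#' CpG-island scan parameters
#'
#' Thresholds are strict (`>`): a window or region qualifies only when GC
#' content exceeds `min_gc` percent and the observed/expected CpG ratio
#' exceeds `min_oe`; reported islands must be longer than `min_length` bases.
#'
#' @param min_gc Minimum GC content, percent (default 50).
#' @param min_oe Minimum observed/expected CpG ratio (default 0.6).
#' @param min_length Minimum island length in bases (default 200).
#' @param window Sliding-window width in bases (default 200).
#' @param step Window step in bases (default 1).
#' @return A list of class `cgi_params`.
#' @export
cgi_params <- function(min_gc = 50, min_oe = 0.6, min_length = 200L,
                       window = 200L, step = 1L) {
  stopifnot(min_gc > 0, min_gc < 100, min_oe > 0,
            min_length >= window, window >= 1L, step >= 1L)
  structure(list(min_gc = min_gc, min_oe = min_oe,
                 min_length = as.integer(min_length),
                 window = as.integer(window), step = as.integer(step)),
            class = "cgi_params")
}

#' GC content of a sequence, in percent
#'
#' `N` bases are excluded from the denominator; an all-`N` sequence returns 0
#' with a warning.
#'
#' @param seq A DNA string (A/C/G/T/N, case-insensitive).
#' @return GC percentage of the non-N bases.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(seq)),
                                   c("G", "C", "N"))
  non_n <- nchar(seq) - f[["N"]]
  if (non_n == 0L) {
    warning("all-N sequence; GC content reported as 0")
    return(0)
  }
  100 * (f[["G"]] + f[["C"]]) / non_n
}

#' Observed/expected CpG ratio
#'
#' Computes `(N_CpG * L) / (N_C * N_G)` where `N_CpG` counts occurrences of
#' the dinucleotide CG, `L` is the number of non-N bases, and `N_C`, `N_G`
#' count C and G. Returns 0 when the sequence contains no C or no G.
#'
#' @param seq A DNA string.
#' @return Dimensionless ratio.
#' @export
obs_exp_cpg <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  s <- Biostrings::DNAString(toupper(seq))
  f <- Biostrings::letterFrequency(s, c("G", "C", "N"))
  if (f[["C"]] == 0 || f[["G"]] == 0) return(0)
  n_cpg <- Biostrings::countPattern("CG", s)
  L <- nchar(seq) - f[["N"]]
  (n_cpg * L) / (f[["C"]] * f[["G"]])
}

# Per-base indicator cumsums used for O(1) interval statistics.
# Returns cumulative counts padded with a leading zero.
cgi_cumsums <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  is_c <- x == "C"
  is_g <- x == "G"
  is_n <- x == "N"
  cg <- if (n > 1L) is_c[-n] & is_g[-1L] else logical(0)
  list(
    n = n,
    C = c(0L, cumsum(is_c)),
    G = c(0L, cumsum(is_g)),
    N = c(0L, cumsum(is_n)),
    CG = c(0L, cumsum(cg)) # index i = CG dinucleotides starting at positions < i
  )
}

# Statistics of the 0-based half-open interval [a, b) from cumsums.
interval_stats <- function(cs, a, b) {
  w <- b - a
  nC <- cs$C[b + 1L] - cs$C[a + 1L]
  nG <- cs$G[b + 1L] - cs$G[a + 1L]
  nN <- cs$N[b + 1L] - cs$N[a + 1L]
  nCG <- if (w >= 2L) cs$CG[b] - cs$CG[a + 1L] else 0L
  non_n <- w - nN
  gc <- if (non_n == 0L) 0 else 100 * (nC + nG) / non_n
  oe <- if (nC == 0L || nG == 0L) 0 else (nCG * non_n) / (nC * nG)
  list(gc = gc, oe = oe, n_frac = nN / w)
}

#' Scan a sequence for CpG islands
#'
#' Slides a window of `params$window` bases by `params$step`; windows pass
#' when GC% and observed/expected CpG both exceed their thresholds (windows
#' more than half `N` never pass). Overlapping or adjacent passing windows are
#' merged, and each merged region is trimmed one base at a time until the
#' whole region satisfies both thresholds. Surviving regions longer than
#' `min_length` are returned sorted by start, non-overlapping.
#'
#' @param seq DNA string (promoter orientation when scanning promoters).
#' @param params [cgi_params()].
#' @return Tibble with `start`, `end` (0-based half-open within `seq`),
#'   `length`, `gc_percent`, `oe_ratio`. Empty when the sequence is shorter
#'   than the window.
#' @export
scan_cgi <- function(seq, params = cgi_params()) {
  stopifnot(inherits(params, "cgi_params"), is.character(seq), length(seq) == 1L)
  empty <- tibble::tibble(start = integer(), end = integer(), length = integer(),
                          gc_percent = double(), oe_ratio = double())
  L <- nchar(seq)
  if (L < params$window) {
    message("sequence shorter than scan window (", L, " < ", params$window,
            "); no islands reported")
    return(empty)
  }
  cs <- cgi_cumsums(seq)
  w <- params$window
  starts <- seq.int(0L, L - w, by = params$step)
  # vectorized window statistics
  nC <- cs$C[starts + w + 1L] - cs$C[starts + 1L]
  nG <- cs$G[starts + w + 1L] - cs$G[starts + 1L]
  nN <- cs$N[starts + w + 1L] - cs$N[starts + 1L]
  nCG <- cs$CG[starts + w] - cs$CG[starts + 1L]
  non_n <- w - nN
  gc <- ifelse(non_n == 0L, 0, 100 * (nC + nG) / non_n)
  oe <- ifelse(nC == 0L | nG == 0L, 0, (nCG * non_n) / (nC * nG))
  ok <- gc > params$min_gc & oe > params$min_oe & nN <= w / 2
  if (!any(ok)) return(empty)
  # merge overlapping or adjacent qualifying windows
  qs <- starts[ok]
  qe <- qs + w
  brk <- c(TRUE, qs[-1L] > qe[-length(qe)])
  grp <- cumsum(brk)
  reg_a <- tapply(qs, grp, min)
  reg_b <- tapply(qe, grp, max)
  out <- vector("list", length(reg_a))
  for (i in seq_along(reg_a)) {
    tr <- trim_region(cs, reg_a[[i]], reg_b[[i]], params)
    if (!is.null(tr)) out[[i]] <- tr
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$start)
}

# Trim [a, b) one base at a time until the whole region passes both
# thresholds; the trimmed side is the one whose removal most increases the
# failing statistic (GC% checked first), ties trimming the 3' (right) end.
# Regions that would fall below min_length are dropped (NULL), as are trimmed
# regions not longer than min_length.
trim_region <- function(cs, a, b, params) {
  repeat {
    st <- interval_stats(cs, a, b)
    if (st$gc > params$min_gc && st$oe > params$min_oe) break
    if (b - a - 1L < params$min_length) return(NULL)
    left <- interval_stats(cs, a + 1L, b)
    right <- interval_stats(cs, a, b - 1L)
    if (st$gc <= params$min_gc) {
      take_left <- left$gc > right$gc
    } else {
      take_left <- left$oe > right$oe
    }
    if (take_left) a <- a + 1L else b <- b - 1L
  }
  if (b - a <= params$min_length) return(NULL)
  st <- interval_stats(cs, a, b)
  tibble::tibble(start = as.integer(a), end = as.integer(b),
                 length = as.integer(b - a),
                 gc_percent = st$gc, oe_ratio = st$oe)
}

#' Does a promoter carry a CpG island sufficiently upstream of the TSS?
#'
#' Islands are assumed scanned on the promoter-oriented sequence (position 0 =
#' most upstream). A gene qualifies when at least one island starts at least
#' `min_upstream_start` bases upstream of the TSS, i.e. at promoter position
#' `<= upstream_len - min_upstream_start`.
#'
#' @param islands Tibble from [scan_cgi()] run on the promoter sequence.
#' @param upstream_len Number of upstream bases in the scanned sequence.
#' @param min_upstream_start Required upstream offset of the island start
#'   (default 200).
#' @return Logical scalar.
#' @export
gene_has_cgi <- function(islands, upstream_len, min_upstream_start = 200L) {
  stopifnot(upstream_len >= 1L, min_upstream_start >= 0L)
  if (nrow(islands) == 0L) return(FALSE)
  any(islands$start <= upstream_len - min_upstream_start)
}

#' Scan promoters and call CGI presence per gene
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param params [cgi_params()].
#' @param min_upstream_start Passed to [gene_has_cgi()].
#' @return Tibble with `gene_id`, `has_cgi`, `n_islands` and, for the island
#'   with the smallest start, `island_start`, `island_end`, `gc_percent`,
#'   `oe_ratio` (NA when no island).
#' @export
scan_promoter_cgi <- function(promoters, params = cgi_params(),
                              min_upstream_start = 200L) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    isl <- suppressMessages(scan_cgi(promoters$sequence[[i]], params))
    has <- gene_has_cgi(isl, promoters$upstream[[i]], min_upstream_start)
    first <- if (nrow(isl)) isl[1L, ] else NULL
    tibble::tibble(
      gene_id = promoters$gene_id[[i]],
      has_cgi = has,
      n_islands = nrow(isl),
      island_start = if (is.null(first)) NA_integer_ else first$start,
      island_end = if (is.null(first)) NA_integer_ else first$end,
      gc_percent = if (is.null(first)) NA_real_ else first$gc_percent,
      oe_ratio = if (is.null(first)) NA_real_ else first$oe_ratio
    )
  })
  dplyr::bind_rows(rows)
}
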