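# Independent oracles: character-vector brute force, no package internals.

oracle_revcomp <- function(seq) {
  x <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  paste(chartr("ACGTN", "TGCAN", x), collapse = "")
}

# Interval statistics computed by direct counting on a character vector;
# `a`, `b` are 0-based half-open.
oracle_stats <- function(x, a, b) {
  w <- x[(a + 1L):b]
  n_c <- sum(w == "C")
  n_g <- sum(w == "G")
  non_n <- sum(w != "N")
  gc <- if (non_n == 0L) 0 else 100 * (n_c + n_g) / non_n
  n_cg <- if (length(w) >= 2L) sum(w[-length(w)] == "C" & w[-1L] == "G") else 0L
  oe <- if (n_c == 0L || n_g == 0L) 0 else n_cg * non_n / (n_c * n_g)
  list(gc = gc, oe = oe, n_frac = sum(w == "N") / length(w))
}

# Brute-force CpG-island scan: enumerate every window, merge overlapping or
# adjacent qualifying windows, then trim each region base by base until it
# passes both thresholds (trim the side whose removal most increases the
# failing statistic, GC first, ties to the 3' end), keeping regions strictly
# longer than min_length.
oracle_scan_cgi <- function(seq, min_gc = 50, min_oe = 0.6, min_length = 200L,
                            window = 200L, step = 1L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(x)
  empty <- data.frame(start = integer(), end = integer())
  if (L < window) return(empty)
  starts <- seq.int(0L, L - window, by = step)
  ok <- vapply(starts, function(s) {
    st <- oracle_stats(x, s, s + window)
    st$n_frac <= 0.5 && st$gc > min_gc && st$oe > min_oe
  }, logical(1L))
  if (!any(ok)) return(empty)
  qs <- starts[ok]
  regions <- list()
  a <- qs[1L]; b <- qs[1L] + window
  for (s in qs[-1L]) {
    if (s <= b) b <- max(b, s + window) else {
      regions[[length(regions) + 1L]] <- c(a, b)
      a <- s; b <- s + window
    }
  }
  regions[[length(regions) + 1L]] <- c(a, b)
  out <- list()
  for (r in regions) {
    a <- r[1L]; b <- r[2L]
    keep <- TRUE
    repeat {
      st <- oracle_stats(x, a, b)
      if (st$gc > min_gc && st$oe > min_oe) break
      if (b - a - 1L < min_length) { keep <- FALSE; break }
      lft <- oracle_stats(x, a + 1L, b)
      rgt <- oracle_stats(x, a, b - 1L)
      if (st$gc <= min_gc) take_left <- lft$gc > rgt$gc
      else take_left <- lft$oe > rgt$oe
      if (take_left) a <- a + 1L else b <- b - 1L
    }
    if (keep && b - a > min_length) {
      out[[length(out) + 1L]] <- data.frame(start = a, end = b)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-element universe whose first K elements form the set, and count subsets
# with at least k hits.
oracle_hypergeom <- function(k, K, n, N) {
  combos <- utils::combn(N, n)
  hits <- colSums(combos <= K)
  mean(hits >= k)
}

# Random DNA string with a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
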