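test_that("gc_content counts G+C over non-N bases", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("acgt"), 50)
  expect_equal(gc_content("GCNN"), 100) # N excluded from denominator
  expect_error(gc_content(""), "empty")
  expect_warning(res <- gc_content("NNNN"), "all-N")
  expect_equal(res, 0)
})

test_that("obs_exp_cpg matches hand counts and conventions", {
  expect_equal(obs_exp_cpg("CGCG"), 2)  # 2 CG, 2 C, 2 G, L = 4
  expect_equal(obs_exp_cpg("CCGG"), 1)  # 1 CG, 2 C, 2 G, L = 4
  expect_equal(obs_exp_cpg("AAAA"), 0)  # no C or G
  expect_error(obs_exp_cpg(""), "empty")
})

test_that("scan_cgi handles degenerate and textbook inputs", {
  params <- cgi_params()
  expect_equal(nrow(scan_cgi(strrep("A", 500), params)), 0L)
  expect_message(res <- scan_cgi("ACGT", params), "shorter")
  expect_equal(nrow(res), 0L)

  isl <- scan_cgi(strrep("CG", 150), params) # 300 bp of alternating CG
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 300L)
  expect_equal(isl$gc_percent, 100)
  expect_equal(isl$oe_ratio, (150 * 300) / (150 * 150))
})

test_that("a planted CG-rich block in AT-rich background yields one island there", {
  set.seed(21)
  for (i in 1:5) {
    bg <- random_dna(1000, gc = 0.2)
    block <- paste(ifelse(runif(200) < 0.35, "CG",
                          sample(c("A", "C", "G", "T"), 200, replace = TRUE)),
                   collapse = "")
    block <- substr(block, 1, 400)
    at <- sample(200:500, 1)
    seq <- paste0(substr(bg, 1, at), block, substr(bg, at + 1, 1000 - 400 + at))
    seq <- substr(seq, 1, 1000)
    isl <- scan_cgi(seq, cgi_params())
    expect_equal(nrow(isl), 1L)
    expect_lt(isl$start, at + 400)
    expect_gt(isl$end, at)
  }
})

test_that("scan_cgi matches the brute-force enumerate-merge-trim oracle", {
  set.seed(22)
  params <- cgi_params()
  for (i in 1:30) {
    n <- sample(300:1500, 1)
    seq <- random_dna(n, gc = runif(1, 0.35, 0.65))
    got <- scan_cgi(seq, params)
    want <- oracle_scan_cgi(seq)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("returned islands re-verify thresholds, ordering and disjointness", {
  set.seed(23)
  params <- cgi_params()
  for (i in 1:10) {
    seq <- random_dna(2000, gc = runif(1, 0.45, 0.6))
    isl <- scan_cgi(seq, params)
    if (nrow(isl) == 0L) next
    for (j in seq_len(nrow(isl))) {
      sub <- substr(seq, isl$start[j] + 1, isl$end[j])
      expect_gt(gc_content(sub), params$min_gc)
      expect_gt(obs_exp_cpg(sub), params$min_oe)
      expect_gt(isl$length[j], params$min_length)
      expect_equal(isl$length[j], isl$end[j] - isl$start[j])
    }
    expect_equal(isl$start, sort(isl$start))
    if (nrow(isl) > 1L) expect_true(all(isl$start[-1] >= isl$end[-nrow(isl)]))
  }
})

test_that("scanning a sequence and its reverse complement mirrors islands", {
  set.seed(24)
  params <- cgi_params()
  for (i in 1:10) {
    n <- sample(500:1500, 1)
    seq <- random_dna(n, gc = runif(1, 0.45, 0.6))
    fwd <- scan_cgi(seq, params)
    rev <- scan_cgi(oracle_revcomp(seq), params)
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd)) {
      expect_equal(sort(n - fwd$end), sort(rev$start))
      expect_equal(sort(n - fwd$start), sort(rev$end))
    }
  }
})

test_that("raising thresholds never increases total island bases", {
  set.seed(25)
  for (i in 1:5) {
    seq <- random_dna(1500, gc = 0.55)
    base <- sum(scan_cgi(seq, cgi_params())$length)
    expect_lte(sum(scan_cgi(seq, cgi_params(min_gc = 60))$length), base)
    expect_lte(sum(scan_cgi(seq, cgi_params(min_oe = 0.9))$length), base)
  }
})

test_that("windows dominated by N never qualify", {
  core <- strrep("CG", 100)
  blurred <- paste0(strrep("N", 150), substr(core, 1, 50))
  seq <- paste0(strrep("A", 300), blurred, strrep("A", 300))
  expect_equal(nrow(scan_cgi(seq, cgi_params())), 0L)
})

test_that("gene_has_cgi applies the upstream-start rule", {
  mk <- function(s, e) tibble::tibble(start = s, end = e, length = e - s,
                                      gc_percent = 60, oe_ratio = 0.8)
  expect_true(gene_has_cgi(mk(0L, 400L), upstream_len = 2000))
  expect_false(gene_has_cgi(mk(1900L, 2000L), upstream_len = 2000))
  expect_true(gene_has_cgi(mk(1800L, 2000L), upstream_len = 2000)) # boundary
  expect_false(gene_has_cgi(mk(integer(0), integer(0)), upstream_len = 2000))
})
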