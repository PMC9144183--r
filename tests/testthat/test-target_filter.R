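test_that("filter_cgi_genes keeps CGI genes in input order", {
  pres <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE, e = TRUE)
  expect_equal(filter_cgi_genes(c("e", "b", "a"), pres), c("e", "a"))
  expect_equal(filter_cgi_genes(character(0), pres), character(0))
  expect_equal(filter_cgi_genes(names(pres), pres[names(pres)] | TRUE),
               names(pres))
  expect_message(out <- filter_cgi_genes(c("a", "zz"), pres), "absent")
  expect_equal(out, "a")
})

test_that("classify_target covers the full 3x3 direction grid", {
  grid <- expand.grid(e = c("up", "down", "none"),
                      m = c("hypomethylated", "hypermethylated", "none"),
                      stringsAsFactors = FALSE)
  got <- classify_target(grid$e, grid$m)
  want <- ifelse(grid$e == "up" & grid$m == "hypomethylated", "oncogene-like",
          ifelse(grid$e == "down" & grid$m == "hypermethylated",
                 "tumor-suppressor-like", "unclassified"))
  expect_equal(got, want)
  expect_error(classify_target("sideways", "none"), "invalid expression")
  expect_error(classify_target("up", "wet"), "invalid methylation")
})

test_that("report carries every DEG and conserves counts", {
  pres <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE)
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         direction = c("up", "down", "up"),
                         log2fc = c(2, -2, 3), q_value = c(0.01, 0.01, 0.01))
  meth <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         direction = c("hypomethylated", "hypermethylated",
                                       "hypomethylated"),
                         delta_beta = c(-0.3, 0.3, -0.3),
                         q_value = c(0.01, 0.01, 0.01))
  rep <- build_target_report(c("g1", "g2", "g3", "g4"), pres, expr, meth)
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$target_class,
               c("oncogene-like", "tumor-suppressor-like",
                 "unclassified",   # concordant but no CGI
                 "unclassified")) # absent from calls
  expect_equal(rep$expr_dir[4], "none")
  s <- summarize_targets(rep)
  expect_equal(s$n_oncogene_like + s$n_tumor_suppressor_like + s$n_unclassified,
               s$n_deg)
})

test_that("pipeline reruns are byte-identical and counts always conserve", {
  dir1 <- file.path(tempdir(), "ppl1"); dir2 <- file.path(tempdir(), "ppl2")
  sim <- simulate_study(seed = 101, out_dir = file.path(tempdir(), "sim101"),
                        n_genes = 20, n_cgi = 10, n_onco = 2, n_tsg = 1,
                        n_up_deg = 10, n_tumor = 8, n_normal = 8)
  cfg <- list(genome = sim$paths$genome, annotation = sim$paths$annotation,
              deg = sim$paths$deg, beta = sim$paths$beta,
              meth_samples = sim$paths$samples, tpm = sim$paths$tpm,
              expr_samples = sim$paths$samples)
  r1 <- run_pipeline(c(cfg, list(out_dir = dir1)))
  r2 <- run_pipeline(c(cfg, list(out_dir = dir2)))
  f1 <- file.path(dir1, "target_report.tsv")
  f2 <- file.path(dir2, "target_report.tsv")
  expect_identical(readLines(f1), readLines(f2))
  s <- r1$summary
  expect_equal(s$n_oncogene_like + s$n_tumor_suppressor_like + s$n_unclassified,
               s$n_deg)
  expect_equal(s$n_deg, 20L)
})

test_that("tightening any threshold never increases classified targets", {
  sim <- simulate_study(seed = 102, n_genes = 30, n_cgi = 15, n_onco = 4,
                        n_tsg = 3, n_up_deg = 15, n_tumor = 10, n_normal = 10,
                        delta_beta = 0.2, lfc = 1.5)
  pres <- {
    genome <- sim$genome
    pr <- extract_promoters(sim$genes, genome)
    cg <- scan_promoter_cgi(pr)
    stats::setNames(cg$has_cgi, cg$gene_id)
  }
  n_classified <- function(q, dbt, lfct) {
    e <- call_expression(sim$expr$tpm, sim$expr$group,
                         lfc_threshold = lfct, q_threshold = q)
    m <- call_methylation(sim$meth$beta, sim$meth$group,
                          delta_threshold = dbt, q_threshold = q)
    rep <- build_target_report(sim$deg$gene_id, pres, e, m)
    sum(rep$target_class != "unclassified")
  }
  base <- n_classified(0.05, 0.1, 1)
  expect_lte(n_classified(0.01, 0.1, 1), base)
  expect_lte(n_classified(0.05, 0.25, 1), base)
  expect_lte(n_classified(0.05, 0.1, 2), base)
  expect_lte(n_classified(0.001, 0.25, 2), base)
})

test_that("precomputed direction tables drive the classifier without matrices", {
  dir <- file.path(tempdir(), "pre")
  dir.create(dir, showWarnings = FALSE)
  deg <- tibble::tibble(gene_id = c("TUBA1B", "RPLP2", "CCN2"),
                        direction = c("up", "up", "down"))
  readr::write_tsv(deg, file.path(dir, "deg.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = deg$gene_id,
                                  has_cgi = c(TRUE, TRUE, FALSE)),
                   file.path(dir, "cgi.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = deg$gene_id,
                                  direction = c("up", "down", "down")),
                   file.path(dir, "expr.tsv"))
  readr::write_tsv(tibble::tibble(
    gene_id = deg$gene_id,
    direction = c("hypomethylated", "hypermethylated", "hypermethylated")
  ), file.path(dir, "meth.tsv"))
  res <- run_pipeline(list(deg = file.path(dir, "deg.tsv"),
                           cgi_presence = file.path(dir, "cgi.tsv"),
                           expression_calls = file.path(dir, "expr.tsv"),
                           methylation_calls = file.path(dir, "meth.tsv")))
  expect_equal(res$report$target_class,
               c("oncogene-like", "tumor-suppressor-like", "unclassified"))
})

test_that("missing inputs produce stage-named errors", {
  expect_error(run_pipeline(list()), "deg")
  expect_error(run_pipeline(list(deg = tempfile())), "not found|cgi|exist",
               ignore.case = TRUE)
})
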