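write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("FASTA reading normalizes case, keeps order, rejects duplicates", {
  p <- write_lines_tmp(c(">c1 extra header words", "acgt", ">c2", "AAAA"), ".fa")
  g <- read_genome_fasta(p)
  expect_equal(names(g), c("c1", "c2"))
  expect_equal(as.character(g[["c1"]]), "ACGT")

  dup <- write_lines_tmp(c(">c1", "ACGT", ">c1", "AAAA"), ".fa")
  expect_error(read_genome_fasta(dup), "duplicate")
  empty <- write_lines_tmp(character(0), ".fa")
  expect_error(read_genome_fasta(empty), "empty")
})

test_that("annotation TSS follows BED and GFF3 conventions per strand", {
  bed <- write_lines_tmp(c("c1\t100\t500\tgeneA\t0\t+",
                           "c1\t100\t500\tgeneB\t0\t-"), ".bed")
  ann <- read_gene_annotation(bed, format = "bed6")
  expect_equal(ann$tss, c(100L, 499L))
  expect_equal(ann$gene_id, c("geneA", "geneB"))

  gff <- write_lines_tmp(c("##gff-version 3",
                           "c1\tsrc\tgene\t101\t500\t.\t+\t.\tID=geneC"),
                         ".gff3")
  ann2 <- read_gene_annotation(gff, format = "gff3")
  expect_equal(ann2$tss, 100L)

  bad <- write_lines_tmp("c1\t100\t500\tgeneA\t0\t.", ".bed")
  expect_error(read_gene_annotation(bad, format = "bed6"), "strand")
})

test_that("TSS outside the contig is rejected when a genome is given", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  bed <- write_lines_tmp("c1\t5\t20\tgeneA\t0\t+", ".bed")
  ann <- read_gene_annotation(bed, format = "bed6", genome = genome)
  expect_equal(ann$tss, 5L)
  bed2 <- write_lines_tmp("c1\t5\t20\tgeneA\t0\t-", ".bed")
  expect_error(read_gene_annotation(bed2, format = "bed6", genome = genome),
               "outside contig")
})

test_that("promoter extraction windows, clipping and orientation are correct", {
  set.seed(11)
  contig <- random_dna(2000)
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  genes <- tibble::tibble(gene_id = c("gPlus", "gEdge"), contig = "c1",
                          strand = "+", tss = c(1000L, 50L))
  pr <- extract_promoters(genes, genome, upstream = 200, downstream = 0)
  expect_equal(pr$start, c(800L, 0L))
  expect_equal(pr$end, c(1000L, 50L))
  expect_equal(pr$clipped, c(FALSE, TRUE))
  expect_equal(pr$sequence[1], substr(contig, 801, 1000))
  expect_equal(nchar(pr$sequence), pr$end - pr$start)
  # length <= upstream with equality iff not clipped
  expect_equal(nchar(pr$sequence) == 200, !pr$clipped)

  expect_error(
    extract_promoters(tibble::tibble(gene_id = "x", contig = "missing",
                                     strand = "+", tss = 10L), genome),
    "absent"
  )
})

test_that("minus-strand promoters are reverse complements of the forward slice", {
  set.seed(12)
  for (i in 1:10) {
    contig <- random_dna(100)
    genome <- Biostrings::DNAStringSet(c(c1 = contig))
    tss <- sample(40:60, 1)
    u <- sample(10:30, 1)
    gene <- tibble::tibble(gene_id = "g", contig = "c1", strand = "-",
                           tss = tss)
    pr <- extract_promoters(gene, genome, upstream = u, downstream = 0)
    fwd_slice <- substr(contig, tss + 2, tss + u + 1)
    expect_equal(pr$sequence, oracle_revcomp(fwd_slice))
  }
})

test_that("strand flip with mirrored TSS yields reverse-complementary promoters", {
  set.seed(13)
  for (i in 1:10) {
    contig <- random_dna(500)
    genome <- Biostrings::DNAStringSet(c(c1 = contig))
    u <- sample(20:80, 1)
    d <- sample(0:20, 1)
    tss <- sample(150:300, 1)
    plus <- tibble::tibble(gene_id = "p", contig = "c1", strand = "+", tss = tss)
    minus <- tibble::tibble(gene_id = "m", contig = "c1", strand = "-",
                            tss = tss - 1L)
    sp <- extract_promoters(plus, genome, upstream = u, downstream = d)
    sm <- extract_promoters(minus, genome, upstream = d, downstream = u)
    # swapped up/down so both windows cover the same forward interval
    expect_equal(sp$start, sm$start)
    expect_equal(sp$end, sm$end)
    expect_equal(sm$sequence, oracle_revcomp(sp$sequence))
  }
})

test_that("promoter FASTA writing round-trips sequences exactly", {
  set.seed(14)
  genome <- Biostrings::DNAStringSet(c(c1 = random_dna(1000)))
  genes <- tibble::tibble(gene_id = paste0("g", 1:4), contig = "c1",
                          strand = c("+", "-", "+", "-"),
                          tss = c(500L, 400L, 800L, 100L))
  pr <- extract_promoters(genes, genome, upstream = 150, downstream = 10)
  fa <- tempfile(fileext = ".fa")
  write_promoters_fasta(pr, fa)
  back <- read_genome_fasta(fa)
  expect_equal(as.character(back), setNames(pr$sequence, pr$gene_id))
})
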