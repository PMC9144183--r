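# Genome and annotation I/O plus strand-aware promoter extraction.
#
# Coordinates are 0-based half-open on the forward strand everywhere inside
# the package; conversions to/from 1-based formats happen only at file
# boundaries.

#' Read a genome FASTA
#'
#' Reads a plain-text FASTA into a `DNAStringSet`. Record names are the header
#' token before the first whitespace; lowercase bases are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty name: ", path)
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate contig name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("zero-length FASTA record in ", path)
  seqs
}

#' Read gene annotation with TSS and strand
#'
#' Accepts BED6 (0-based half-open) or minimal GFF3 (1-based inclusive;
#' `gene` features). The transcription start site is the feature start on the
#' `+` strand and the rightmost feature base on the `-` strand, reported as a
#' 0-based forward-strand coordinate.
#'
#' @param path Annotation file.
#' @param format `"bed6"` or `"gff3"` (default guesses from the extension).
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when given,
#'   contigs and TSS coordinates are validated against it.
#' @return Tibble with columns `gene_id`, `contig`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed6", "gff3"),
                                 genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed6"
  }
  gr <- switch(format,
    bed6 = rtracklayer::import(path, format = "BED"),
    gff3 = {
      g <- rtracklayer::import(path, format = "GFF3")
      if ("type" %in% names(S4Vectors::mcols(g))) {
        g <- g[as.character(g$type) == "gene"]
      }
      g
    }
  )
  if (length(gr) == 0L) stop("no gene records in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol in ", path, " (need '+' or '-')")
  }
  ids <- if (format == "bed6") as.character(gr$name) else {
    mc <- S4Vectors::mcols(gr)
    if ("ID" %in% names(mc)) as.character(mc$ID)
    else if ("Name" %in% names(mc)) as.character(mc$Name)
    else stop("GFF3 gene records need an ID or Name attribute: ", path)
  }
  if (any(is.na(ids) | !nzchar(ids))) stop("missing gene id in ", path)
  # GRanges are 1-based inclusive regardless of the on-disk convention
  tss <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  genes <- tibble::tibble(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss)
  )
  if (!is.null(genome)) {
    missing <- setdiff(genes$contig, names(genome))
    if (length(missing)) {
      stop("annotation contig(s) absent from genome: ",
           paste(unique(missing), collapse = ", "))
    }
    len <- Biostrings::width(genome)[match(genes$contig, names(genome))]
    bad <- genes$tss < 0L | genes$tss >= len
    if (any(bad)) {
      stop("TSS outside contig for gene(s): ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
  }
  genes
}

#' Extract strand-oriented promoter regions
#'
#' For each gene, takes `upstream` bases upstream and `downstream` bases
#' downstream of the TSS and returns the sequence in promoter (transcription)
#' orientation: position 0 of the returned sequence is the most-upstream base,
#' and minus-strand promoters are reverse-complemented. Windows running off a
#' contig edge are clipped and flagged.
#'
#' @param genes Tibble from [read_gene_annotation()] (columns `gene_id`,
#'   `contig`, `strand`, `tss`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param upstream Bases upstream of the TSS (>= 1; default 2000).
#' @param downstream Bases downstream of (and including) the TSS (default 0).
#' @return Tibble with `gene_id`, `contig`, `start`, `end` (0-based half-open,
#'   forward strand), `strand`, `clipped`, `upstream` (actual upstream extent
#'   after clipping) and `sequence`.
#' @export
extract_promoters <- function(genes, genome, upstream = 2000L, downstream = 0L) {
  stopifnot(upstream >= 1L, downstream >= 0L)
  missing <- setdiff(genes$contig, names(genome))
  if (length(missing)) {
    stop("gene contig(s) absent from genome: ",
         paste(unique(missing), collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(genes$contig, names(genome))]
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  end0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  cs <- pmax(start0, 0L)
  ce <- pmin(end0, clen)
  if (any(cs >= ce)) {
    stop("promoter window empty after clipping for gene(s): ",
         paste(genes$gene_id[cs >= ce], collapse = ", "))
  }
  fwd <- as.character(Biostrings::subseq(genome[genes$contig],
                                         start = cs + 1L, end = ce))
  seqs <- ifelse(plus, fwd, revcomp(fwd))
  tibble::tibble(
    gene_id = genes$gene_id,
    contig = genes$contig,
    start = as.integer(cs),
    end = as.integer(ce),
    strand = genes$strand,
    clipped = cs != start0 | ce != end0,
    upstream = as.integer(ifelse(plus, genes$tss - cs, ce - 1L - genes$tss)),
    sequence = unname(seqs)
  )
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- promoters$gene_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write promoter intervals as BED6
#'
#' Intervals are forward-strand, 0-based half-open, with the gene id in the
#' name column.
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output BED path.
#' @export
write_promoters_bed <- function(promoters, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = promoters$contig,
    ranges = IRanges::IRanges(start = promoters$start + 1L, end = promoters$end),
    strand = promoters$strand,
    name = promoters$gene_id,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
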