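# Synthetic study generator: genomes with planted promoter CpG islands,
# tumor/normal beta and TPM matrices with planted group effects, and a DEG
# table, all deterministic under a seed, with the planted truth recorded so
# every pipeline stage can be scored against it.

# Sample one CpG-depleted AT-rich background base string of length n.
# Dinucleotide CG occurrences are broken with probability `deplete` by
# replacing the G with A or T.
background_sequence <- function(n, gc = 0.35, deplete = 0.9) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(p), n, replace = TRUE, prob = p)
  cg <- which(x[-n] == "C" & x[-1L] == "G")
  if (length(cg)) {
    hit <- cg[stats::runif(length(cg)) < deplete]
    if (length(hit)) {
      x[hit + 1L] <- sample(c("A", "T"), length(hit), replace = TRUE)
    }
  }
  paste(x, collapse = "")
}

# Sample a CG-rich island string: tokens are the literal dinucleotide "CG"
# with probability cg_rate, otherwise a single base whose C/G probability is
# solved so the overall GC fraction hits `gc`.
island_sequence <- function(len, gc = 0.65, cg_rate = 0.25) {
  s <- (gc * (1 + cg_rate) - 2 * cg_rate) / (1 - cg_rate)
  if (s < 0 || s > 1) {
    stop("island GC target ", gc, " unreachable with cg_rate ", cg_rate)
  }
  p <- c(A = (1 - s) / 2, C = s / 2, G = s / 2, T = (1 - s) / 2)
  n_tok <- ceiling(len)
  toks <- ifelse(stats::runif(n_tok) < cg_rate, "CG",
                 sample(names(p), n_tok, replace = TRUE, prob = p))
  substr(paste(toks, collapse = ""), 1L, len)
}

#' Generate a synthetic genome with planted promoter CpG islands
#'
#' One contig per gene: CpG-depleted AT-rich background with, for a planted
#' fraction of genes, a CG-rich block inside the promoter window whose start
#' lies well over 200 bp upstream of the TSS. Both strands are represented;
#' output is deterministic under the seed.
#'
#' @param n_genes Number of genes/contigs (default 51).
#' @param frac_cgi Fraction of genes with a planted island (default 24/51).
#' @param seed Integer seed.
#' @param upstream Promoter window length the islands are planted into
#'   (default 2000).
#' @param background_gc Background GC fraction (default 0.35).
#' @param island_gc Island GC fraction (default 0.65; must be >= 0.6 for
#'   comfortable margin over the 50% criterion).
#' @param island_len Island length in bases (default 500; must be >= 300).
#' @param contig_len Contig length (default 4000).
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes` (tibble:
#'   `gene_id`, `contig`, `strand`, `tss`) and `truth` (tibble with
#'   `cgi_planted`, planted island promoter-orientation coordinates, and
#'   zeroed effect columns to be filled by [plant_effects()]).
#' @export
generate_genome <- function(n_genes = 51L, frac_cgi = 24 / 51, seed = 1L,
                            upstream = 2000L, background_gc = 0.35,
                            island_gc = 0.65, island_len = 500L,
                            contig_len = 4000L) {
  stopifnot(n_genes >= 1L, frac_cgi >= 0, frac_cgi <= 1,
            island_gc >= 0.6, island_len >= 300L)
  if (island_len > upstream) stop("island longer than promoter window")
  if (contig_len < upstream + 1000L) stop("contig too short for promoter window")
  n_cgi <- round(frac_cgi * n_genes)
  with_seed(seed, {
    cgi_idx <- if (n_cgi > 0) sort(sample.int(n_genes, n_cgi)) else integer(0)
    ids <- sprintf("gene%03d", seq_len(n_genes))
    strands <- rep(c("+", "-"), length.out = n_genes)
    tss <- ifelse(strands == "+", contig_len - 1000L, 999L)
    seqs <- character(n_genes)
    isl_start <- rep(NA_integer_, n_genes)
    isl_end <- rep(NA_integer_, n_genes)
    for (i in seq_len(n_genes)) {
      bg <- background_sequence(contig_len, gc = background_gc)
      if (i %in% cgi_idx) {
        # promoter-orientation start: >= 200 bp of island upstream margin and
        # the whole island at least 300 bp clear of the TSS
        p_max <- upstream - island_len - 300L
        p <- sample.int(p_max - 100L + 1L, 1L) + 99L # uniform on [100, p_max]
        isl <- island_sequence(island_len, gc = island_gc)
        if (strands[i] == "+") {
          # promoter-orientation position p -> forward coord tss - upstream + p
          f0 <- tss[i] - upstream + p
          substr(bg, f0 + 1L, f0 + island_len) <- isl
        } else {
          # promoter position p -> forward coords; island occupies
          # [tss + upstream - p - len + 1, tss + upstream - p + 1) on forward
          f0 <- tss[i] + upstream - p - island_len + 1L
          substr(bg, f0 + 1L, f0 + island_len) <- revcomp(isl)
        }
        isl_start[i] <- p
        isl_end[i] <- p + island_len
      }
      seqs[i] <- bg
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr_", ids)
    genes <- tibble::tibble(gene_id = ids, contig = names(genome),
                            strand = strands, tss = as.integer(tss))
    truth <- tibble::tibble(
      gene_id = ids,
      cgi_planted = seq_len(n_genes) %in% cgi_idx,
      island_start = isl_start,
      island_end = isl_end,
      planted_delta_beta = 0,
      planted_log2fc = 0,
      intended_class = "unclassified"
    )
    list(genome = genome, genes = genes, truth = truth)
  })
}

#' Plant tumor-vs-normal effects consistent with intended target classes
#'
#' Among CGI-planted genes, the first `n_onco` receive concordant activation
#' (planted log2fc `+lfc`, delta beta `-delta_beta`; intended oncogene-like)
#' and the next `n_tsg` concordant silencing (intended
#' tumor-suppressor-like). Remaining CGI genes cycle through discordant and
#' null effect pairs; CGI-free genes cycle through null and concordant pairs
#' (which must stay unclassified for want of an island), exercising every
#' branch of the classifier. `intended_class` is derived from the planted
#' signs and island status via the classification truth table.
#'
#' @param truth Truth tibble from [generate_genome()].
#' @param n_onco,n_tsg Numbers of intended oncogene-like and
#'   tumor-suppressor-like genes (defaults 5 and 2).
#' @param delta_beta Magnitude of the planted beta shift (default 0.3).
#' @param lfc Magnitude of the planted log2 fold change (default 2).
#' @return The truth tibble with effect columns and `intended_class` filled.
#' @export
plant_effects <- function(truth, n_onco = 5L, n_tsg = 2L, delta_beta = 0.3,
                          lfc = 2) {
  stopifnot(delta_beta >= 0, delta_beta <= 0.48, lfc >= 0)
  cgi <- which(truth$cgi_planted)
  if (length(cgi) < n_onco + n_tsg) {
    stop("need at least ", n_onco + n_tsg, " CGI-planted genes")
  }
  db <- truth$planted_delta_beta
  fc <- truth$planted_log2fc
  onco <- cgi[seq_len(n_onco)]
  tsg <- cgi[n_onco + seq_len(n_tsg)]
  db[onco] <- -delta_beta; fc[onco] <- lfc
  db[tsg] <- delta_beta;   fc[tsg] <- -lfc
  rest <- setdiff(cgi, c(onco, tsg))
  if (length(rest)) {
    pat <- (seq_along(rest) - 1L) %% 3L
    db[rest] <- c(delta_beta, -delta_beta, 0)[pat + 1L]
    fc[rest] <- c(lfc, -lfc, 0)[pat + 1L]      # up+hyper, down+hypo, null
  }
  free <- which(!truth$cgi_planted)
  if (length(free)) {
    pat <- (seq_along(free) - 1L) %% 3L
    db[free] <- c(0, -delta_beta, delta_beta)[pat + 1L]
    fc[free] <- c(0, lfc, -lfc)[pat + 1L]      # null, up+hypo, down+hyper
  }
  expr_dir <- dplyr::case_when(fc > 0 ~ "up", fc < 0 ~ "down", TRUE ~ "none")
  meth_dir <- dplyr::case_when(db < 0 ~ "hypomethylated",
                               db > 0 ~ "hypermethylated", TRUE ~ "none")
  cls <- classify_target(expr_dir, meth_dir)
  cls[!truth$cgi_planted] <- "unclassified"
  truth$planted_delta_beta <- db
  truth$planted_log2fc <- fc
  truth$intended_class <- cls
  truth
}

#' Generate a tumor/normal methylation dataset with planted beta shifts
#'
#' Per gene, the normal-group mean beta is 0.5 and the tumor mean is shifted
#' by `planted_delta_beta` (means clipped to `[0.02, 0.98]`); samples are
#' drawn from a Beta distribution parameterized by mean and concentration.
#'
#' @param truth Truth tibble with `planted_delta_beta`.
#' @param n_tumor,n_normal Samples per group (defaults 20/20).
#' @param concentration Beta-distribution concentration (alpha + beta;
#'   default 20 — sd about 0.11 at mean 0.5).
#' @param seed Integer seed.
#' @return List with `beta` (genes x samples matrix) and `group` (named
#'   vector of `tumor`/`normal`).
#' @export
generate_methylation <- function(truth, n_tumor = 20L, n_normal = 20L,
                                 concentration = 20, seed = 1L) {
  stopifnot(concentration > 0, n_tumor >= 1L, n_normal >= 1L)
  if (any(abs(truth$planted_delta_beta) > 1)) stop("invalid beta shift")
  clip <- function(x) pmin(pmax(x, 0.02), 0.98)
  with_seed(seed, {
    n_genes <- nrow(truth)
    mu_n <- rep(0.5, n_genes)
    mu_t <- clip(0.5 + truth$planted_delta_beta)
    draw <- function(mu, n) {
      t(vapply(mu, function(m) {
        stats::rbeta(n, shape1 = m * concentration,
                     shape2 = (1 - m) * concentration)
      }, numeric(n)))
    }
    beta <- cbind(draw(mu_t, n_tumor), draw(mu_n, n_normal))
    rownames(beta) <- truth$gene_id
    colnames(beta) <- c(sprintf("tumor_%02d", seq_len(n_tumor)),
                        sprintf("normal_%02d", seq_len(n_normal)))
    group <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                             colnames(beta))
    list(beta = beta, group = group)
  })
}

#' Generate a tumor/normal TPM expression dataset with planted fold changes
#'
#' Normal-group gene means are log-uniform on 1-1000 TPM; genes carrying a
#' planted fold change are drawn from 10-1000 TPM so the planted direction is
#' not erased by the pseudocount shrinkage that any fold-change estimate
#' applies near the detection floor. The tumor mean is the normal mean times
#' `2^planted_log2fc`; per-sample noise is log2-normal with standard
#' deviation `sigma_log`.
#'
#' @param truth Truth tibble with `planted_log2fc`.
#' @param n_tumor,n_normal Samples per group (defaults 20/20).
#' @param sigma_log Log2-scale noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return List with `tpm` (genes x samples matrix) and `group`.
#' @export
generate_expression <- function(truth, n_tumor = 20L, n_normal = 20L,
                                sigma_log = 0.5, seed = 1L) {
  stopifnot(sigma_log > 0, n_tumor >= 1L, n_normal >= 1L)
  with_seed(seed, {
    n_genes <- nrow(truth)
    lo <- ifelse(truth$planted_log2fc != 0, 1, 0) # effect genes >= 10 TPM
    mu_n <- 10^stats::runif(n_genes, lo, 3)
    mu_t <- mu_n * 2^truth$planted_log2fc
    draw <- function(mu, n) {
      t(vapply(mu, function(m) m * 2^stats::rnorm(n, 0, sigma_log),
               numeric(n)))
    }
    tpm <- cbind(draw(mu_t, n_tumor), draw(mu_n, n_normal))
    rownames(tpm) <- truth$gene_id
    colnames(tpm) <- c(sprintf("tumor_%02d", seq_len(n_tumor)),
                       sprintf("normal_%02d", seq_len(n_normal)))
    group <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                             colnames(tpm))
    list(tpm = tpm, group = group)
  })
}

#' Generate paired allele-intensity matrices realizing target beta values
#'
#' Inverse of [beta_value()]: `m = beta * total`, `u = (1 - beta) * total`,
#' optionally with multiplicative log-normal noise. In the noiseless case
#' `beta_value(m, u, 0)` recovers the targets exactly.
#'
#' @param beta_targets Numeric vector or matrix of betas in `[0, 1]`.
#' @param total_intensity Total intensity per measurement (default 1000).
#' @param noise_cv Coefficient of variation of multiplicative noise
#'   (default 0 = noiseless).
#' @param seed Integer seed (only used when `noise_cv > 0`).
#' @return List with `methylated` and `unmethylated`, shaped like the input.
#' @export
generate_intensities <- function(beta_targets, total_intensity = 1000,
                                 noise_cv = 0, seed = 1L) {
  stopifnot(all(beta_targets >= 0), all(beta_targets <= 1), total_intensity > 0,
            noise_cv >= 0)
  m <- beta_targets * total_intensity
  u <- (1 - beta_targets) * total_intensity
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, {
      m <- m * exp(stats::rnorm(length(m), -sdl^2 / 2, sdl))
      u <- u * exp(stats::rnorm(length(u), -sdl^2 / 2, sdl))
    })
  }
  list(methylated = m, unmethylated = u)
}

#' Simulate a full synthetic study and optionally write it to disk
#'
#' The default configuration mirrors the flow-chart shape of the motivating
#' analysis: 51 DEGs (25 up / 26 down in the input list), 24 genes with a
#' planted promoter island, and among those 5 concordant-activated and 2
#' concordant-silenced genes, with 20 tumor / 20 normal samples per modality.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir When set, writes `genome.fa`, `genes.bed`, `deg.tsv`,
#'   `beta.tsv`, `tpm.tsv`, `samples.tsv` and `truth.tsv` there.
#' @param n_genes,n_cgi,n_onco,n_tsg Study-shape counts.
#' @param n_up_deg Up-regulated genes in the input DEG table (default 25).
#' @param n_tumor,n_normal Samples per group.
#' @param delta_beta,lfc Planted effect magnitudes.
#' @param concentration,sigma_log Noise parameters.
#' @param ... Further arguments to [generate_genome()].
#' @return List with `genome`, `genes`, `truth`, `deg`, `meth`, `expr` and
#'   (when written) `paths`.
#' @export
simulate_study <- function(seed = 1L, out_dir = NULL, n_genes = 51L,
                           n_cgi = 24L, n_onco = 5L, n_tsg = 2L,
                           n_up_deg = 25L, n_tumor = 20L, n_normal = 20L,
                           delta_beta = 0.3, lfc = 2, concentration = 20,
                           sigma_log = 0.5, ...) {
  gen <- generate_genome(n_genes = n_genes, frac_cgi = n_cgi / n_genes,
                         seed = seed, ...)
  truth <- plant_effects(gen$truth, n_onco = n_onco, n_tsg = n_tsg,
                         delta_beta = delta_beta, lfc = lfc)
  meth <- generate_methylation(truth, n_tumor = n_tumor, n_normal = n_normal,
                               concentration = concentration, seed = seed + 1L)
  expr <- generate_expression(truth, n_tumor = n_tumor, n_normal = n_normal,
                              sigma_log = sigma_log, seed = seed + 2L)
  # input DEG table: up/down split of the serum-treatment screen feeding the
  # pipeline; independent of the planted tumor/normal effects
  deg <- with_seed(seed + 3L, {
    dirs <- rep(c("up", "down"), c(n_up_deg, n_genes - n_up_deg))
    tibble::tibble(
      gene_id = truth$gene_id,
      log2fc = ifelse(dirs == "up", 1, -1) * stats::runif(n_genes, 0.5, 3),
      p_value = stats::runif(n_genes, 1e-5, 0.04),
      direction = dirs
    )
  })
  out <- list(genome = gen$genome, genes = gen$genes, truth = truth,
              deg = deg, meth = meth, expr = expr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      annotation = file.path(out_dir, "genes.bed"),
      deg = file.path(out_dir, "deg.tsv"),
      beta = file.path(out_dir, "beta.tsv"),
      tpm = file.path(out_dir, "tpm.tsv"),
      samples = file.path(out_dir, "samples.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    Biostrings::writeXStringSet(gen$genome, paths$genome)
    # gene features: 500-bp bodies whose strand-aware start recovers the TSS
    gr <- GenomicRanges::GRanges(
      seqnames = gen$genes$contig,
      ranges = IRanges::IRanges(
        start = ifelse(gen$genes$strand == "+", gen$genes$tss,
                       gen$genes$tss - 499L) + 1L,
        width = 500L
      ),
      strand = gen$genes$strand,
      name = gen$genes$gene_id,
      score = 0L
    )
    rtracklayer::export(gr, paths$annotation, format = "BED")
    readr::write_tsv(deg, paths$deg)
    write_mat <- function(mat, path) {
      df <- tibble::as_tibble(mat, rownames = "gene_id")
      readr::write_tsv(df, path)
    }
    write_mat(meth$beta, paths$beta)
    write_mat(expr$tpm, paths$tpm)
    readr::write_tsv(tibble::tibble(sample = names(meth$group),
                                    group = unname(meth$group)),
                     paths$samples)
    readr::write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}
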