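# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without side effects.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a numeric genes-by-samples matrix from TSV or CSV
#'
#' First column holds gene identifiers (used as row names); remaining columns
#' are samples. The delimiter is taken from the file extension (`.csv` for
#' comma, anything else tab).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_matrix_table <- function(path) {
  stopifnot(file.exists(path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a gene-id column plus >= 1 sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a sample sheet mapping samples to tumor/normal groups
#'
#' Expects a two-column TSV with header `sample` and `group`; groups must be
#' `tumor` or `normal`.
#'
#' @param path Path to the sample-sheet TSV.
#' @return Named character vector of groups, names being sample ids.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("sample sheet must have columns 'sample' and 'group': ", path)
  }
  grp <- as.character(df$group)
  bad <- setdiff(unique(grp), c("tumor", "normal"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  stats::setNames(grp, as.character(df$sample))
}

# Align a group vector with a matrix's columns; errors on mismatch.
match_groups <- function(mat, group) {
  if (!is.null(names(group)) && !is.null(colnames(mat))) {
    missing <- setdiff(colnames(mat), names(group))
    if (length(missing)) {
      stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
    }
    group <- group[colnames(mat)]
  }
  if (length(group) != ncol(mat)) {
    stop("group labels (", length(group), ") do not match matrix columns (",
         ncol(mat), ")")
  }
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  as.character(group)
}
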