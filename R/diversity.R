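# Sliding-window nucleotide diversity over a multiple alignment, projected
# onto the ungapped coordinates of a chosen reference sequence.

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA (all sequences equal length).
#' @return Named character vector of aligned sequences (upper-case, U
#'   normalized to T, gaps kept).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  x <- toupper(as.character(seqs))
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub(".", "-", x, fixed = TRUE)
  names(x) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(x))) > 1) {
    stop("sequences are not aligned: unequal lengths", call. = FALSE)
  }
  x
}

.aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (!is.character(alignment)) stop("alignment must be a character vector or matrix",
                                     call. = FALSE)
  if (length(unique(nchar(alignment))) > 1) {
    stop("sequences are not aligned: unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Nucleotide diversity of an aligned block
#'
#' Average pairwise difference per site:
#' `pi = sum_{i<j} d_ij / C(n,2) / L_eff`, where `d_ij` counts differing
#' valid site pairs and `L_eff` is the mean number of valid paired sites.
#' Under pairwise deletion (default) a site is valid for a pair when both
#' bases are in A/C/G/T; under complete deletion only columns valid in all
#' sequences are used.
#'
#' @param alignment Character vector (or character matrix) of aligned,
#'   equal-length sequences; at least two.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Nucleotide diversity in \[0, 1\]; `NA` when no valid paired
#'   sites exist (e.g. an all-gap window).
#' @export
nucleotide_diversity <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 aligned sequences", call. = FALSE)
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  if (deletion == "complete") {
    keep <- apply(valid, 2, all)
    if (!any(keep)) return(NA_real_)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  total_diff <- 0
  total_len <- 0
  n_pairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      total_diff <- total_diff + sum(m[i, ok] != m[j, ok])
      total_len <- total_len + sum(ok)
      n_pairs <- n_pairs + 1L
    }
  }
  if (total_len == 0) return(NA_real_)
  (total_diff / n_pairs) / (total_len / n_pairs)
}

# Remove 1-based inclusive column ranges given as a list of c(start, end)
# or an n x 2 matrix.
.drop_columns <- function(m, ranges) {
  if (is.null(ranges) || length(ranges) == 0) return(m)
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
  if (!is.list(ranges)) ranges <- list(ranges)
  drop <- unique(unlist(lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || r[1] > r[2]) stop("malformed column range", call. = FALSE)
    if (r[2] > ncol(m)) stop("column range exceeds alignment width", call. = FALSE)
    seq.int(max(1L, r[1]), r[2])
  })))
  m[, -drop, drop = FALSE]
}

#' Sliding-window nucleotide diversity profile
#'
#' Slides a fixed window along the alignment (after optional removal of
#' large-indel column ranges) and computes [nucleotide_diversity()] per
#' window. Window bounds are projected onto the ungapped coordinates of the
#' reference sequence; windows containing no reference base are skipped.
#'
#' @param alignment Named character vector or character matrix of aligned
#'   sequences.
#' @param reference_id Name of the reference sequence used for the
#'   coordinate projection.
#' @param window_bp Window size in alignment columns (default 99).
#' @param step_bp Step size in alignment columns (default 10).
#' @param drop_column_ranges Optional list of 1-based inclusive
#'   `c(start, end)` alignment-column ranges removed before sliding.
#' @param deletion Gap handling passed to [nucleotide_diversity()].
#' @return A `pi_profile` tibble: `window`, `aln_start`, `aln_end`,
#'   `ref_start`, `ref_end` (1-based inclusive on the ungapped reference)
#'   and `pi`.
#' @export
sliding_pi <- function(alignment, reference_id, window_bp = 99, step_bp = 10,
                       drop_column_ranges = NULL,
                       deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .aln_matrix(alignment)
  if (is.null(rownames(m)) || !reference_id %in% rownames(m)) {
    stop("reference sequence not present in alignment: ", reference_id,
         call. = FALSE)
  }
  m <- .drop_columns(m, drop_column_ranges)
  L <- ncol(m)
  if (window_bp > L) stop("window larger than alignment", call. = FALSE)
  ref <- m[reference_id, ]
  ref_base <- !ref %in% c("-", ".")
  ref_pos <- cumsum(ref_base)          # ungapped ref index at each column
  starts <- seq.int(1L, L - window_bp + 1L, by = step_bp)
  rows <- purrr::map(seq_along(starts), function(w) {
    a <- starts[w]; b <- a + window_bp - 1L
    cols <- a:b
    in_win <- which(ref_base[cols])
    if (length(in_win) == 0) return(NULL)
    tibble::tibble(
      window = w,
      aln_start = a, aln_end = b,
      ref_start = ref_pos[cols[in_win[1]]],
      ref_end = ref_pos[cols[in_win[length(in_win)]]],
      pi = nucleotide_diversity(m[, cols, drop = FALSE], deletion = deletion)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  structure(out, class = c("pi_profile", class(tibble::tibble())),
            reference_id = reference_id, window_bp = window_bp,
            step_bp = step_bp)
}

#' Plot a nucleotide diversity profile
#'
#' @param object A `pi_profile` from [sliding_pi()].
#' @param ... Unused.
#' @return A ggplot object: pi against the reference midpoint position.
#' @export
autoplot.pi_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$mid <- (d$ref_start + d$ref_end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$pi)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = sprintf("Position on %s (bp)", attr(object, "reference_id")),
      y = expression(pi),
      title = "Sliding-window nucleotide diversity"
    ) +
    ggplot2::theme_minimal()
}

#' Write a pi profile as TSV
#'
#' @param profile A `pi_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pi_profile <- function(profile, path) {
  .write_atomic(function(tmp) {
    utils::write.table(tibble::as_tibble(profile), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }, path)
}
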