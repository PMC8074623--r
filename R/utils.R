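# Shared sequence utilities: IUPAC alphabet handling, bit-mask encoding for
# degeneracy-aware matching, reverse complement, and reporting-grade rounding.

# Bit masks: A=1, C=2, G=4, T=8. Degenerate codes are unions. N carries an
# extra bit (16) so that a primer N matches a target N (and any base) while
# other degenerate primer codes never match a target N.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 31L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# Expected G+C content of each IUPAC code (uniform over its set).
.IUPAC_GC <- c(
  A = 0, C = 1, G = 1, T = 0,
  R = 0.5, Y = 0.5, S = 1, W = 0, K = 0.5, M = 0.5,
  B = 2 / 3, D = 1 / 3, H = 1 / 3, V = 2 / 3, N = 0.5
)

#' Normalize a nucleotide string
#'
#' Upper-cases, converts U to T and strips gap characters (`-`, `.`).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of cleaned sequences.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- gsub("[-.]", "", x)
  gsub("U", "T", x, fixed = TRUE)
}

.check_iupac <- function(x, what = "sequence") {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, names(.IUPAC_BITS))
  if (length(bad) > 0) {
    stop(sprintf("illegal character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes are complemented set-wise (R to Y, B to V, ...).
#'
#' @param x Character vector of IUPAC nucleotide strings (5' to 3').
#' @return Character vector of reverse complements (5' to 3').
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- .IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) stop("cannot complement non-IUPAC character", call. = FALSE)
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Encode a sequence as integer bit masks. Primers keep the full degenerate
# union (N = matches anything); targets get N and friends restricted so that
# an unknown target base is only matched by a primer N.
.encode <- function(s, role = c("target", "primer")) {
  role <- match.arg(role)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) stop("non-IUPAC character in sequence", call. = FALSE)
  bits <- unname(bits)
  if (role == "target") {
    # target N (or any code containing the N sentinel) matches only primer N
    bits[chars == "N"] <- 16L
  }
  bits
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.845 -> 0.85 at 2 digits),
#' matching how the indices are reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Atomic write helper: write to a temp file in the same directory, then rename.
.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
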