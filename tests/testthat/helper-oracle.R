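# Independent brute-force oracles, implemented with character-set lookups
# (no bit masks) and plain per-offset loops, deliberately separate from the
# package's matching engine.

.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

# logical match matrix: rows primer chars, cols target chars
.oracle_matrix <- local({
  letters <- names(.oracle_sets)
  m <- matrix(FALSE, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (p in letters) {
    for (t in letters) {
      if (t == "N") {
        m[p, t] <- p == "N"
      } else {
        m[p, t] <- length(intersect(.oracle_sets[[p]],
                                    setdiff(.oracle_sets[[t]], "N"))) > 0
      }
    }
  }
  m
})

oracle_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all start positions where primer matches target with <= max_mm mismatches
# and zero mismatches at the (1-based, window-relative) strict positions
oracle_sites <- function(target, primer, max_mm, strict_idx) {
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  n <- length(tc); m <- length(pc)
  out_start <- integer(0); out_mm <- integer(0)
  if (n < m) return(list(start = out_start, mismatches = out_mm))
  for (s in 1:(n - m + 1)) {
    ok <- .oracle_matrix[cbind(pc, tc[s:(s + m - 1)])]
    mm <- sum(!ok)
    if (mm <= max_mm && all(ok[strict_idx])) {
      out_start <- c(out_start, s)
      out_mm <- c(out_mm, mm)
    }
  }
  list(start = out_start, mismatches = out_mm)
}

# full-scan amplification oracle; returns a tibble comparable to amplify()
oracle_amplify <- function(db, pair, amplicon_min, amplicon_max) {
  lf <- nchar(pair$forward); lr <- nchar(pair$reverse)
  tps <- pair$three_prime_strict
  f_strict <- if (tps > 0) (lf - min(tps, lf) + 1):lf else integer(0)
  r_strict <- if (tps > 0) 1:min(tps, lr) else integer(0)
  rev_site <- oracle_revcomp(pair$reverse)
  rows <- list()
  for (ri in seq_len(nrow(db$records))) {
    for (strand in c("+", "-")) {
      s <- db$records$sequence[ri]
      if (strand == "-") s <- oracle_revcomp(s)
      f <- oracle_sites(s, pair$forward, pair$max_mismatches, f_strict)
      r <- oracle_sites(s, rev_site, pair$max_mismatches, r_strict)
      if (length(f$start) == 0 || length(r$start) == 0) next
      for (i in seq_along(f$start)) {
        for (j in seq_along(r$start)) {
          ins_len <- r$start[j] - (f$start[i] + lf)
          if (ins_len >= amplicon_min && ins_len <= amplicon_max) {
            rows <- c(rows, list(tibble::tibble(
              record_id = db$records$record_id[ri],
              strand = strand,
              fwd_start = f$start[i], fwd_mismatches = f$mismatches[i],
              rev_start = r$start[j], rev_mismatches = r$mismatches[j],
              insert = substr(s, f$start[i] + lf, r$start[j] - 1),
              insert_length_bp = ins_len
            )))
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(record_id = character(0), strand = character(0),
                          fwd_start = integer(0), fwd_mismatches = integer(0),
                          rev_start = integer(0), rev_mismatches = integer(0),
                          insert = character(0), insert_length_bp = integer(0)))
  }
  dplyr::bind_rows(rows)
}

# canonical ordering for hit-table comparison
sort_hits <- function(tab) {
  cols <- c("record_id", "strand", "fwd_start", "rev_start",
            "fwd_mismatches", "rev_mismatches", "insert", "insert_length_bp")
  tab <- tibble::as_tibble(lapply(stats::setNames(cols, cols),
                                  function(cl) tab[[cl]]))
  tab <- dplyr::mutate(tab, dplyr::across(c("fwd_start", "rev_start",
                                            "fwd_mismatches", "rev_mismatches",
                                            "insert_length_bp"), as.integer))
  dplyr::arrange(tab, record_id, strand, fwd_start, rev_start)
}

# random IUPAC primer: ACGT with a few degenerate positions
random_primer <- function(len, n_degenerate = 0) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0) {
    pos <- sample.int(len, n_degenerate)
    chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), n_degenerate,
                         replace = TRUE)
  }
  paste(chars, collapse = "")
}
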