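# Mismatch-tolerant in-silico PCR: degeneracy-aware primer-site matching with
# a 3'-anchored exact region, convergent-orientation pairing on both strands,
# and insert extraction.

#' Define a primer pair for in-silico PCR
#'
#' @param name Pair name.
#' @param forward,reverse IUPAC primer strings, both written 5' to 3'. The
#'   reverse primer is given on the opposite strand, as ordered for PCR.
#' @param max_mismatches Mismatch budget per primer site.
#' @param three_prime_strict Number of 3'-terminal primer positions that
#'   must match exactly.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatches = 0,
                        three_prime_strict = 0) {
  forward <- normalize_sequence(forward)
  reverse <- normalize_sequence(reverse)
  if (nchar(forward) == 0 || nchar(reverse) == 0) {
    stop("primer sequences must be non-empty", call. = FALSE)
  }
  .check_iupac(forward, "forward primer")
  .check_iupac(reverse, "reverse primer")
  stopifnot(max_mismatches >= 0, three_prime_strict >= 0)
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches),
                 three_prime_strict = as.integer(three_prime_strict)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F 5'-%s-3'\n  R 5'-%s-3'\n  max mismatches %d, 3'-strict %d\n",
              x$name, x$forward, x$reverse, x$max_mismatches, x$three_prime_strict))
  invisible(x)
}

# Find all start positions (1-based) where `primer_enc` matches `target_enc`
# with at most `max_mm` mismatches and zero mismatches among the
# `tps` positions indexed by `strict_idx` (positions within the primer
# window). Returns a list(start, mismatches).
.match_sites <- function(target_enc, primer_enc, max_mm, strict_idx) {
  n <- length(target_enc); m <- length(primer_enc)
  if (n < m) return(list(start = integer(0), mismatches = integer(0)))
  n_off <- n - m + 1L
  mm <- integer(n_off)
  strict_ok <- rep(TRUE, n_off)
  for (i in seq_len(m)) {
    miss <- bitwAnd(primer_enc[i], target_enc[i:(i + n_off - 1L)]) == 0L
    mm <- mm + miss
    if (i %in% strict_idx) strict_ok <- strict_ok & !miss
  }
  keep <- mm <= max_mm & strict_ok
  list(start = which(keep), mismatches = mm[keep])
}

# Scan one target strand (already oriented so the forward primer reads left
# to right) for convergent primer-site pairs delimiting an insert within
# the length bounds.
.scan_strand <- function(target_enc, fwd_enc, rev_site_enc, pair,
                         amplicon_min, amplicon_max) {
  lf <- length(fwd_enc); lr <- length(rev_site_enc)
  tps <- pair$three_prime_strict
  # forward primer: 3' end is the right edge of its window
  f_strict <- if (tps > 0) seq.int(lf - min(tps, lf) + 1L, lf) else integer(0)
  # reverse site is revcomp(reverse primer): the primer's 3' end maps to the
  # left edge of the site window
  r_strict <- if (tps > 0) seq.int(1L, min(tps, lr)) else integer(0)
  f <- .match_sites(target_enc, fwd_enc, pair$max_mismatches, f_strict)
  if (length(f$start) == 0) return(NULL)
  r <- .match_sites(target_enc, rev_site_enc, pair$max_mismatches, r_strict)
  if (length(r$start) == 0) return(NULL)
  out <- vector("list", length(f$start))
  for (i in seq_along(f$start)) {
    fs <- f$start[i]
    insert_start <- fs + lf
    ins_len <- r$start - insert_start          # vector over reverse sites
    ok <- ins_len >= amplicon_min & ins_len <= amplicon_max
    if (!any(ok)) next
    out[[i]] <- tibble::tibble(
      fwd_start = fs, fwd_mismatches = f$mismatches[i],
      rev_start = r$start[ok], rev_mismatches = r$mismatches[ok],
      insert_start = insert_start, insert_length_bp = ins_len[ok]
    )
  }
  out <- purrr::compact(out)
  if (length(out) == 0) NULL else dplyr::bind_rows(out)
}

#' In-silico amplification of a reference database
#'
#' Scans every record on both strands for convergent matches of the primer
#' pair: the forward primer matched directly, the reverse primer via its
#' reverse complement downstream, each with at most `max_mismatches`
#' mismatches and the last `three_prime_strict` primer positions exact.
#' Degenerate primer positions match any target base in their IUPAC set
#' (a target `N` matches only a primer `N`). All site pairs delimiting an
#' insert within `[amplicon_min, amplicon_max]` are reported.
#'
#' @param db A `ref_db`.
#' @param pair A [primer_pair()].
#' @param amplicon_min,amplicon_max Insert-length bounds in bp (primer
#'   sites excluded).
#' @return An `amplicon_table`: tibble of hits with columns `record_id`,
#'   `taxid`, `strand`, `fwd_start`, `fwd_mismatches`, `rev_start`,
#'   `rev_mismatches`, `insert`, `insert_length_bp`, `full_length_bp`.
#'   Coordinates are 1-based positions of the 5' end of each primer site on
#'   the scanned strand. The primer pair and bounds are carried in
#'   attributes for downstream evaluation.
#' @export
amplify <- function(db, pair, amplicon_min = 50, amplicon_max = 200) {
  stopifnot(inherits(db, "ref_db"), inherits(pair, "primer_pair"))
  if (amplicon_min > amplicon_max) {
    stop("amplicon bounds inverted: amplicon_min > amplicon_max", call. = FALSE)
  }
  fwd_enc <- .encode(pair$forward, "primer")
  rev_site_enc <- .encode(revcomp(pair$reverse), "primer")
  rows <- purrr::pmap(db$records[, c("record_id", "sequence", "taxid")],
    function(record_id, sequence, taxid) {
      strands <- list(`+` = sequence, `-` = revcomp(sequence))
      purrr::imap(strands, function(s, strand) {
        enc <- .encode(s, "target")
        hits <- .scan_strand(enc, fwd_enc, rev_site_enc, pair,
                             amplicon_min, amplicon_max)
        if (is.null(hits)) return(NULL)
        hits$insert <- substring(s, hits$insert_start,
                                 hits$insert_start + hits$insert_length_bp - 1L)
        hits$record_id <- record_id
        hits$taxid <- taxid
        hits$strand <- strand
        hits
      })
    })
  hits <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(
      record_id = character(0), taxid = integer(0), strand = character(0),
      fwd_start = integer(0), fwd_mismatches = integer(0),
      rev_start = integer(0), rev_mismatches = integer(0),
      insert = character(0), insert_length_bp = integer(0),
      full_length_bp = integer(0)
    )
  } else {
    hits$full_length_bp <- hits$insert_length_bp +
      nchar(pair$forward) + nchar(pair$reverse)
    hits <- hits[, c("record_id", "taxid", "strand", "fwd_start",
                     "fwd_mismatches", "rev_start", "rev_mismatches",
                     "insert", "insert_length_bp", "full_length_bp")]
  }
  structure(hits,
            class = c("amplicon_table", class(tibble::tibble()))) |>
    .set_amplify_attrs(pair, amplicon_min, amplicon_max)
}

.set_amplify_attrs <- function(x, pair, amplicon_min, amplicon_max) {
  attr(x, "pair") <- pair
  attr(x, "amplicon_min") <- amplicon_min
  attr(x, "amplicon_max") <- amplicon_max
  x
}

#' Per-taxon amplification summary
#'
#' @param db A `ref_db`.
#' @param table An `amplicon_table` from [amplify()].
#' @return Tibble with one row per taxon unit: record counts, amplified
#'   record counts and the number of distinct insert sequences.
#' @export
summarize_amplicons <- function(db, table) {
  units <- .record_units(db)
  hits <- dplyr::left_join(tibble::as_tibble(table),
                           units[, c("record_id", "unit_taxid")],
                           by = "record_id")
  per_rec <- dplyr::distinct(units[!is.na(units$unit_taxid),
                                   c("record_id", "unit_taxid")])
  rec_counts <- dplyr::count(per_rec, .data$unit_taxid, name = "n_records")
  amp <- hits[!is.na(hits$unit_taxid), , drop = FALSE]
  amp_counts <- dplyr::summarize(
    dplyr::group_by(amp, .data$unit_taxid),
    n_amplified_records = dplyr::n_distinct(.data$record_id),
    n_distinct_inserts = dplyr::n_distinct(.data$insert),
    .groups = "drop"
  )
  out <- dplyr::left_join(rec_counts, amp_counts, by = "unit_taxid")
  out$n_amplified_records[is.na(out$n_amplified_records)] <- 0L
  out$n_distinct_inserts[is.na(out$n_distinct_inserts)] <- 0L
  out
}

#' Write amplification hits as TSV and inserts as FASTA
#'
#' Emitted coordinates are 1-based inclusive.
#'
#' @param table An `amplicon_table`.
#' @param tsv_path,fasta_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_amplicons <- function(table, tsv_path = NULL, fasta_path = NULL) {
  tab <- tibble::as_tibble(table)
  if (!is.null(tsv_path)) {
    .write_atomic(function(tmp) {
      utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }, tsv_path)
  }
  if (!is.null(fasta_path) && nrow(tab) > 0) {
    seqs <- Biostrings::BStringSet(tab$insert)
    names(seqs) <- sprintf("%s taxid=%d; strand=%s; mismatches=%d+%d",
                           tab$record_id, tab$taxid, tab$strand,
                           tab$fwd_mismatches, tab$rev_mismatches)
    .write_atomic(function(tmp) Biostrings::writeXStringSet(seqs, tmp), fasta_path)
  }
  invisible(c(tsv_path, fasta_path))
}
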