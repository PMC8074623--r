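# Candidate primer-pair enumeration: quorum-based seeding of conserved words
# from the database itself, convergent pairing under the mismatch budget,
# and ranking by estimated coverage and specificity.

#' Discovery parameters
#'
#' Parameter set for candidate enumeration. Two database regimes are
#' shipped via [discovery_preset()]: `genbank_exact` (quorums 0.7/0.9,
#' 0 mismatches), `genbank_mm3` (quorums 0.7/0.9, 3 mismatches, 2 strict
#' 3'-matches) and `silva_relaxed` (quorums 0.5/0.7, 3 mismatches, 2 strict
#' 3'-matches). The two GenBank settings correspond to two independent
#' enumeration runs; their outputs are not merged.
#'
#' @param primer_length_bp Primer word length (default 20).
#' @param amplicon_min_bp,amplicon_max_bp Insert-length bounds (50-200).
#' @param strict_quorum Minimum fraction of records containing a candidate
#'   word exactly (either strand).
#' @param sensitivity_quorum Minimum fraction of records a candidate pair
#'   must amplify within the mismatch budget.
#' @param max_mismatches Mismatch budget per primer site during pairing.
#' @param three_prime_strict Exact 3'-terminal matches required.
#' @param max_words Cap on the number of seeded words carried into the
#'   quadratic pairing stage (highest record support first).
#' @return A `discovery_params` list.
#' @export
discovery_params <- function(primer_length_bp = 20, amplicon_min_bp = 50,
                             amplicon_max_bp = 200, strict_quorum = 0.7,
                             sensitivity_quorum = 0.9, max_mismatches = 0,
                             three_prime_strict = 0, max_words = 500) {
  stopifnot(strict_quorum >= 0, strict_quorum <= 1,
            sensitivity_quorum >= 0, sensitivity_quorum <= 1,
            amplicon_min_bp <= amplicon_max_bp,
            three_prime_strict <= primer_length_bp)
  structure(list(primer_length_bp = as.integer(primer_length_bp),
                 amplicon_min_bp = as.integer(amplicon_min_bp),
                 amplicon_max_bp = as.integer(amplicon_max_bp),
                 strict_quorum = strict_quorum,
                 sensitivity_quorum = sensitivity_quorum,
                 max_mismatches = as.integer(max_mismatches),
                 three_prime_strict = as.integer(three_prime_strict),
                 max_words = as.integer(max_words)),
            class = "discovery_params")
}

#' @rdname discovery_params
#' @param name Preset name.
#' @export
discovery_preset <- function(name = c("genbank_exact", "genbank_mm3",
                                      "silva_relaxed")) {
  name <- match.arg(name)
  switch(name,
    genbank_exact = discovery_params(strict_quorum = 0.7,
                                     sensitivity_quorum = 0.9,
                                     max_mismatches = 0,
                                     three_prime_strict = 0),
    genbank_mm3 = discovery_params(strict_quorum = 0.7,
                                   sensitivity_quorum = 0.9,
                                   max_mismatches = 3,
                                   three_prime_strict = 2),
    silva_relaxed = discovery_params(strict_quorum = 0.5,
                                     sensitivity_quorum = 0.7,
                                     max_mismatches = 3,
                                     three_prime_strict = 2)
  )
}

# Unique A/C/G/T words of length k present in a single sequence (one strand).
.record_words <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  w <- substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  unique(w[!grepl("[^ACGT]", w)])
}

#' Enumerate conserved candidate words
#'
#' A word of the configured length is retained when it occurs exactly
#' (0 mismatches, counted per record, either strand) in at least
#' `strict_quorum` of the database records.
#'
#' @param db A `ref_db`.
#' @param params A [discovery_params()] object.
#' @return Tibble (`word`, `n_records`, `record_fraction`) sorted by
#'   decreasing support, word as tie-break.
#' @export
enumerate_words <- function(db, params = discovery_params()) {
  stopifnot(inherits(db, "ref_db"))
  if (nrow(db$records) == 0) stop("empty database", call. = FALSE)
  k <- params$primer_length_bp
  per_record <- purrr::map(db$records$sequence, function(s) {
    unique(c(.record_words(s, k), .record_words(revcomp(s), k)))
  })
  counts <- table(unlist(per_record, use.names = FALSE))
  n <- nrow(db$records)
  keep <- counts[counts / n >= params$strict_quorum]
  out <- tibble::tibble(
    word = names(keep),
    n_records = as.integer(keep),
    record_fraction = as.integer(keep) / n
  )
  dplyr::arrange(out, dplyr::desc(.data$n_records), .data$word)
}

#' Pair candidate words into ranked primer candidates
#'
#' An ordered pair (w1, w2) is kept when, in at least `sensitivity_quorum`
#' of the records, w1 and the reverse complement of w2 match (within the
#' mismatch budget, 3'-anchored) in convergent orientation on the same
#' strand, delimiting an insert within the amplicon bounds. Each kept pair
#' is re-scored with [amplify()] and [evaluate()]; candidates are ranked by
#' estimated coverage then specificity (descending), with alphabetical
#' tie-break on forward then reverse sequence.
#'
#' @param db A `ref_db`.
#' @param words Tibble from [enumerate_words()] (or character vector).
#' @param params A [discovery_params()] object.
#' @return Tibble of candidates: `forward`, `reverse`, `est_bc`, `est_bs`,
#'   `n_records_supporting`, `median_amplicon_bp`.
#' @export
pair_candidates <- function(db, words, params = discovery_params()) {
  stopifnot(inherits(db, "ref_db"))
  if (is.data.frame(words)) words <- words$word
  if (length(words) == 0) {
    return(tibble::tibble(forward = character(0), reverse = character(0),
                          est_bc = numeric(0), est_bs = numeric(0),
                          n_records_supporting = integer(0),
                          median_amplicon_bp = integer(0)))
  }
  words <- utils::head(words, params$max_words)
  n_rec <- nrow(db$records)
  k <- params$primer_length_bp
  tps <- params$three_prime_strict
  f_strict <- if (tps > 0) seq.int(k - tps + 1L, k) else integer(0)
  r_strict <- if (tps > 0) seq.int(1L, tps) else integer(0)
  enc_fwd <- lapply(words, .encode, role = "primer")
  enc_rc <- lapply(revcomp(words), .encode, role = "primer")

  support <- new.env(parent = emptyenv())
  for (ri in seq_len(n_rec)) {
    seqs <- c(db$records$sequence[ri], revcomp(db$records$sequence[ri]))
    seen <- character(0)
    for (s in seqs) {
      enc <- .encode(s, "target")
      fpos <- lapply(enc_fwd, function(p)
        .match_sites(enc, p, params$max_mismatches, f_strict)$start)
      rpos <- lapply(enc_rc, function(p)
        .match_sites(enc, p, params$max_mismatches, r_strict)$start)
      have_f <- which(lengths(fpos) > 0)
      have_r <- which(lengths(rpos) > 0)
      for (i in have_f) {
        ends <- fpos[[i]] + k - 1L
        for (j in have_r) {
          ins <- outer(rpos[[j]], ends, `-`) - 1L
          if (any(ins >= params$amplicon_min_bp & ins <= params$amplicon_max_bp)) {
            seen <- c(seen, paste(words[i], words[j], sep = "|"))
          }
        }
      }
    }
    for (key in unique(seen)) {
      support[[key]] <- (if (is.null(support[[key]])) 0L else support[[key]]) + 1L
    }
  }
  keys <- ls(support)
  if (length(keys) == 0) {
    return(tibble::tibble(forward = character(0), reverse = character(0),
                          est_bc = numeric(0), est_bs = numeric(0),
                          n_records_supporting = integer(0),
                          median_amplicon_bp = integer(0)))
  }
  counts <- vapply(keys, function(kk) support[[kk]], integer(1))
  keep <- counts / n_rec >= params$sensitivity_quorum
  keys <- keys[keep]; counts <- counts[keep]
  parts <- stringr::str_split_fixed(keys, stringr::fixed("|"), 2)
  out <- purrr::map_dfr(seq_along(keys), function(i) {
    pr <- primer_pair(paste0("candidate_", i), parts[i, 1], parts[i, 2],
                      max_mismatches = params$max_mismatches,
                      three_prime_strict = params$three_prime_strict)
    tab <- amplify(db, pr, params$amplicon_min_bp, params$amplicon_max_bp)
    rep <- evaluate(db, tab)
    tibble::tibble(
      forward = parts[i, 1], reverse = parts[i, 2],
      est_bc = rep$bc_raw,
      est_bs = ifelse(is.na(rep$bs_raw), 0, rep$bs_raw),
      n_records_supporting = counts[i],
      median_amplicon_bp = if (nrow(tab) > 0)
        as.integer(round(stats::median(tab$insert_length_bp))) else NA_integer_
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$est_bc), dplyr::desc(.data$est_bs),
                 .data$forward, .data$reverse)
}

#' End-to-end candidate discovery
#'
#' Convenience wrapper: [enumerate_words()] then [pair_candidates()].
#'
#' @inheritParams pair_candidates
#' @return Ranked candidate tibble.
#' @export
discover_primers <- function(db, params = discovery_params()) {
  pair_candidates(db, enumerate_words(db, params), params)
}
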