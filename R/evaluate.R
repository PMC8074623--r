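# Taxon-level evaluation of an in-silico amplification: coverage and
# specificity indices, ambiguity groups labelled by their shared taxonomic
# rank, and the two non-amplification failure modes.

#' Coverage index
#'
#' Fraction of target taxa amplified, `n_amplified / n_target`, reported
#' rounded half-up to two decimals.
#'
#' @param n_amplified,n_target Taxon counts; `n_target` must be positive.
#' @return Rounded coverage index.
#' @export
coverage_index <- function(n_amplified, n_target) {
  if (n_target <= 0) stop("zero denominator: n_target must be > 0", call. = FALSE)
  round_half_up(n_amplified / n_target, 2)
}

#' Specificity index
#'
#' Fraction of amplified taxa identified unambiguously,
#' `n_identified / n_amplified`, reported rounded half-up to two decimals.
#'
#' @param n_identified,n_amplified Taxon counts; `n_amplified` must be
#'   positive.
#' @return Rounded specificity index.
#' @export
specificity_index <- function(n_identified, n_amplified) {
  if (n_amplified <= 0) stop("zero denominator: n_amplified must be > 0", call. = FALSE)
  round_half_up(n_identified / n_amplified, 2)
}

# Minimal union-find for ambiguity components.
.components <- function(ids, edges) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(match(edges[[1]][k], ids))
      b <- find(match(edges[[2]][k], ids))
      if (a != b) parent[[b]] <- a
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  split(ids, roots)
}

#' Evaluate an amplification against the taxon universe
#'
#' A taxon unit is AMPLIFIED when at least one of its records yields a hit,
#' and IDENTIFIED when, additionally, none of its distinct insert sequences
#' is exactly equal (string equality after normalization) to an insert of
#' another taxon. Taxa sharing inserts form ambiguity groups (connected
#' components of the shared-insert relation), each labelled with the lowest
#' common taxonomic rank of its members. Non-amplified taxa are split into
#' those lacking the target region entirely (no record matches either
#' primer-site probe within `probe_max_mismatches`) and those whose region
#' is present but unamplified.
#'
#' @param db A `ref_db`.
#' @param table An `amplicon_table` produced from `db` by [amplify()].
#' @param region_probe Character vector of one or more probe sequences
#'   marking the target region (defaults to the two primer annealing sites
#'   of the pair used for amplification).
#' @param probe_max_mismatches Mismatch tolerance of the region probe
#'   (default 3).
#' @return An `eval_report` object; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
evaluate <- function(db, table, region_probe = NULL, probe_max_mismatches = 3) {
  stopifnot(inherits(db, "ref_db"))
  pair <- attr(table, "pair")
  if (is.null(region_probe)) {
    if (is.null(pair)) stop("region_probe required when the amplicon table carries no primer pair",
                            call. = FALSE)
    region_probe <- c(pair$forward, revcomp(pair$reverse))
  }
  tt <- target_taxa(db)
  units <- .record_units(db)
  hits <- dplyr::left_join(tibble::as_tibble(table),
                           units[, c("record_id", "unit_taxid")],
                           by = "record_id")
  hits <- hits[!is.na(hits$unit_taxid), , drop = FALSE]

  inserts <- dplyr::distinct(hits[, c("unit_taxid", "insert")])
  amplified <- sort(unique(inserts$unit_taxid))

  # shared-insert relation between distinct taxa
  shared <- dplyr::inner_join(inserts, inserts, by = "insert",
                              relationship = "many-to-many")
  shared <- shared[shared$unit_taxid.x < shared$unit_taxid.y,
                   c("unit_taxid.x", "unit_taxid.y")]
  shared <- dplyr::distinct(shared)
  ambiguous_taxa <- sort(unique(c(shared$unit_taxid.x, shared$unit_taxid.y)))
  identified <- setdiff(amplified, ambiguous_taxa)

  groups <- tibble::tibble(group = integer(0), taxids = list(),
                           shared_rank = character(0))
  if (length(ambiguous_taxa) > 0) {
    comp <- unname(.components(ambiguous_taxa, shared))
    comp <- comp[order(vapply(comp, min, numeric(1)))]
    groups <- tibble::tibble(
      group = seq_along(comp),
      taxids = lapply(comp, as.integer),
      shared_rank = unname(vapply(comp, function(g) lowest_common_rank(db, g),
                                  character(1)))
    )
  }

  # failure modes among non-amplified taxa
  not_amplified <- setdiff(tt$key_taxid, amplified)
  missing_region <- integer(0)
  region_present <- integer(0)
  if (length(not_amplified) > 0) {
    probes <- lapply(region_probe, .encode, role = "primer")
    has_region <- function(unit) {
      recs <- units$record_id[!is.na(units$unit_taxid) & units$unit_taxid == unit]
      seqs <- db$records$sequence[db$records$record_id %in% recs]
      for (s in seqs) {
        for (st in c(s, revcomp(s))) {
          enc <- .encode(st, "target")
          for (p in probes) {
            m <- .match_sites(enc, p, probe_max_mismatches, integer(0))
            if (length(m$start) > 0) return(TRUE)
          }
        }
      }
      FALSE
    }
    present <- vapply(not_amplified, has_region, logical(1))
    missing_region <- not_amplified[!present]
    region_present <- not_amplified[present]
  }

  n_target <- nrow(tt)
  n_amplified <- length(amplified)
  n_identified <- length(identified)

  classification <- tibble::tibble(
    key_taxid = tt$key_taxid,
    rank_of_key = tt$rank_of_key,
    name = tt$name,
    status = "not_amplified_missing_region"
  )
  classification$status[classification$key_taxid %in% region_present] <-
    "not_amplified_region_present"
  classification$status[classification$key_taxid %in% identified] <- "identified"
  if (nrow(groups) > 0) {
    for (k in seq_len(nrow(groups))) {
      sel <- classification$key_taxid %in% groups$taxids[[k]]
      classification$status[sel] <- paste0("ambiguous_", groups$shared_rank[k])
    }
  }

  structure(list(
    n_target_taxa = n_target,
    n_amplified_taxa = n_amplified,
    n_identified_taxa = n_identified,
    bc = coverage_index(n_amplified, n_target),
    bs = if (n_amplified > 0) specificity_index(n_identified, n_amplified) else NA_real_,
    bc_raw = n_amplified / n_target,
    bs_raw = if (n_amplified > 0) n_identified / n_amplified else NA_real_,
    amplified_taxa = amplified,
    identified_taxa = identified,
    ambiguity_groups = groups,
    not_amplified_region_present = sort(region_present),
    not_amplified_missing_region = sort(missing_region),
    classification = classification,
    marker_name = if (!is.null(pair)) pair$name else NA_character_
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s\n", x$marker_name))
  cat(sprintf("  target taxa      %d\n", x$n_target_taxa))
  cat(sprintf("  amplified taxa   %d  (Bc = %.2f)\n", x$n_amplified_taxa, x$bc))
  cat(sprintf("  identified taxa  %d  (Bs = %.2f)\n", x$n_identified_taxa, x$bs))
  cat(sprintf("  ambiguity groups %d; missing region %d; region present, unamplified %d\n",
              nrow(x$ambiguity_groups), length(x$not_amplified_missing_region),
              length(x$not_amplified_region_present)))
  invisible(x)
}

#' Tidy a primer evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Per-taxon tibble with the classification (`identified`,
#'   `ambiguous_genus`, `ambiguous_family`, `ambiguous_higher`,
#'   `not_amplified_region_present`, `not_amplified_missing_region`).
#' @export
tidy.eval_report <- function(x, ...) x$classification

#' One-row summary of a primer evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with taxon counts and indices.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    marker = x$marker_name,
    n_target_taxa = x$n_target_taxa,
    n_amplified_taxa = x$n_amplified_taxa,
    n_identified_taxa = x$n_identified_taxa,
    bc = x$bc, bs = x$bs
  )
}

#' Write an evaluation report as JSON plus a per-taxon TSV
#'
#' @param report An `eval_report`.
#' @param json_path JSON output path (`NULL` to skip).
#' @param tsv_path Per-taxon classification TSV path (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      schema_version = 1L,
      marker = report$marker_name,
      n_target_taxa = report$n_target_taxa,
      n_amplified_taxa = report$n_amplified_taxa,
      n_identified_taxa = report$n_identified_taxa,
      bc = report$bc, bs = report$bs,
      bc_raw = report$bc_raw, bs_raw = report$bs_raw,
      amplified_taxa = report$amplified_taxa,
      identified_taxa = report$identified_taxa,
      ambiguity_groups = lapply(seq_len(nrow(report$ambiguity_groups)), function(k) {
        list(taxids = report$ambiguity_groups$taxids[[k]],
             shared_rank = report$ambiguity_groups$shared_rank[k])
      }),
      not_amplified_region_present = report$not_amplified_region_present,
      not_amplified_missing_region = report$not_amplified_missing_region
    )
    .write_atomic(function(tmp) {
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    }, json_path)
  }
  if (!is.null(tsv_path)) {
    .write_atomic(function(tmp) {
      utils::write.table(report$classification, tmp, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }, tsv_path)
  }
  invisible(c(json_path, tsv_path))
}

#' Read an evaluation report written by [write_eval_report()]
#'
#' @param path JSON path.
#' @return A list with the report fields (taxid vectors as integers).
#' @export
read_eval_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
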