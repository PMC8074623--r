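# Reference database model: taxonomically annotated sequence records plus a
# parent/rank/name taxonomy table, with lineage resolution and the taxon-unit
# definition used by the coverage/specificity indices.

.RANKS <- c("species", "genus", "family", "order", "class", "no_rank")

#' Read a taxonomy table
#'
#' Parses a 4-column TSV (`taxid`, `parent_taxid`, `rank`, `name`) describing
#' a rooted taxonomy. The root node is its own parent; every other node's
#' parent must be present; ranks are drawn from
#' `species, genus, family, order, class, no_rank`.
#'
#' @param path Path to the TSV file (header row required).
#' @return A tibble with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_taxonomy(tibble::as_tibble(tab))
}

#' Validate a taxonomy tibble
#'
#' @param taxonomy A data frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`.
#' @return The validated taxonomy as a tibble (invisibly usable downstream).
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(taxonomy))) {
    stop("malformed taxonomy: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  taxonomy$taxid <- as.integer(taxonomy$taxid)
  taxonomy$parent_taxid <- as.integer(taxonomy$parent_taxid)
  if (anyNA(taxonomy$taxid) || anyNA(taxonomy$parent_taxid) ||
      any(taxonomy$taxid <= 0)) {
    stop("malformed taxonomy row: taxids must be positive integers",
         call. = FALSE)
  }
  if (anyDuplicated(taxonomy$taxid)) {
    stop("malformed taxonomy: duplicate taxid", call. = FALSE)
  }
  bad_rank <- setdiff(unique(taxonomy$rank), .RANKS)
  if (length(bad_rank) > 0) {
    stop("malformed taxonomy: unknown rank(s) ",
         paste(bad_rank, collapse = ", "), call. = FALSE)
  }
  roots <- taxonomy$taxid[taxonomy$taxid == taxonomy$parent_taxid]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one root (its own parent)", call. = FALSE)
  }
  orphan <- setdiff(taxonomy$parent_taxid, taxonomy$taxid)
  if (length(orphan) > 0) {
    stop("malformed taxonomy: parent taxid(s) missing: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  taxonomy
}

#' Convert an NCBI-style taxonomy dump to the 4-column table
#'
#' Reads `nodes.dmp` / `names.dmp` style pipe-delimited files (fields
#' separated by `\t|\t`) and returns the compact `taxid`, `parent_taxid`,
#' `rank`, `name` table used throughout the package. Ranks outside the
#' supported enumeration are mapped to `no_rank`; only scientific names are
#' kept.
#'
#' @param nodes_path Path to a `nodes.dmp`-style file.
#' @param names_path Path to a `names.dmp`-style file.
#' @return A validated taxonomy tibble.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  if (!file.exists(nodes_path)) stop("file not found: ", nodes_path, call. = FALSE)
  if (!file.exists(names_path)) stop("file not found: ", names_path, call. = FALSE)
  split_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nodes <- split_dmp(nodes_path)
  names_rows <- split_dmp(names_path)
  nm <- purrr::keep(names_rows, ~ length(.x) >= 4 && .x[[4]] == "scientific name")
  name_map <- stats::setNames(
    purrr::map_chr(nm, 2),
    purrr::map_chr(nm, 1)
  )
  tab <- tibble::tibble(
    taxid = as.integer(purrr::map_chr(nodes, 1)),
    parent_taxid = as.integer(purrr::map_chr(nodes, 2)),
    rank = purrr::map_chr(nodes, 3),
    name = unname(name_map[purrr::map_chr(nodes, 1)])
  )
  tab$rank[!tab$rank %in% .RANKS] <- "no_rank"
  tab$name[is.na(tab$name)] <- paste0("taxid_", tab$taxid[is.na(tab$name)])
  validate_taxonomy(tab)
}

#' Load an annotated reference database
#'
#' Reads a FASTA file whose headers carry a `taxid=<int>;` token (OBITools
#' style) or, alternatively, a 2-column sidecar TSV mapping `record_id` to
#' `taxid`, together with a taxonomy table. Sequences are upper-cased, U is
#' normalized to T and gap characters are stripped. Records whose taxid does
#' not resolve in the taxonomy are dropped and counted in the load report.
#'
#' @param fasta_path Path to the FASTA file.
#' @param taxonomy_path Path to the taxonomy TSV (see [read_taxonomy()]).
#' @param taxid_map_path Optional path to a headerless or headered 2-column
#'   TSV (`record_id`, `taxid`) used when headers carry no taxid token.
#' @return A `ref_db` object: list with tibbles `records` (`record_id`,
#'   `sequence`, `taxid`, `length_bp`), `taxonomy`, and a `report` list of
#'   load counts.
#' @export
load_reference <- function(fasta_path, taxonomy_path, taxid_map_path = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path, call. = FALSE)
  taxonomy <- read_taxonomy(taxonomy_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty database: no FASTA records", call. = FALSE)
  headers <- names(seqs)
  record_id <- sub("\\s.*$", "", headers)
  taxid <- suppressWarnings(
    as.integer(stringr::str_match(headers, "taxid=(\\d+)")[, 2])
  )
  if (!is.null(taxid_map_path)) {
    map <- utils::read.delim(taxid_map_path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (identical(tolower(as.character(map[1, 1])), "record_id")) map <- map[-1, ]
    lk <- stats::setNames(as.integer(map[[2]]), as.character(map[[1]]))
    fill <- is.na(taxid) & record_id %in% names(lk)
    taxid[fill] <- lk[record_id[fill]]
  }
  records <- tibble::tibble(
    record_id = record_id,
    sequence = normalize_sequence(unname(as.character(seqs))),
    taxid = taxid
  )
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record_id in FASTA", call. = FALSE)
  }
  resolvable <- !is.na(records$taxid) & records$taxid %in% taxonomy$taxid
  dropped <- records$record_id[!resolvable]
  records <- records[resolvable, , drop = FALSE]
  records$length_bp <- nchar(records$sequence)
  if (nrow(records) == 0) stop("empty database: no annotatable records", call. = FALSE)
  db <- new_ref_db(records, taxonomy,
                   report = list(n_loaded = nrow(records),
                                 n_dropped = length(dropped),
                                 dropped_records = dropped))
  db$report$n_target_taxa <- nrow(target_taxa(db))
  db
}

#' Construct a reference database from in-memory tables
#'
#' @param records Tibble with `record_id`, `sequence`, `taxid` (and
#'   optionally `length_bp`).
#' @param taxonomy Taxonomy tibble (see [validate_taxonomy()]).
#' @param report Optional list of load statistics.
#' @return A `ref_db` object.
#' @export
new_ref_db <- function(records, taxonomy, report = list()) {
  taxonomy <- validate_taxonomy(taxonomy)
  records <- tibble::as_tibble(records)
  records$sequence <- normalize_sequence(records$sequence)
  records$length_bp <- nchar(records$sequence)
  if (anyDuplicated(records$record_id)) stop("duplicate record_id", call. = FALSE)
  if (!all(records$taxid %in% taxonomy$taxid)) {
    stop("record taxid does not resolve in taxonomy", call. = FALSE)
  }
  structure(list(records = records, taxonomy = taxonomy, report = report),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  tt <- target_taxa(x)
  cat(sprintf("<ref_db> %d records, %d taxonomy nodes, %d target taxa\n",
              nrow(x$records), nrow(x$taxonomy), nrow(tt)))
  invisible(x)
}

#' Write the load report as JSON
#'
#' @param db A `ref_db`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_load_report <- function(db, path) {
  rep <- db$report
  rep$n_records <- nrow(db$records)
  rep$n_taxa <- nrow(target_taxa(db))
  .write_atomic(function(tmp) {
    jsonlite::write_json(rep, tmp, auto_unbox = TRUE, pretty = TRUE)
  }, path)
}

#' Lineage of a taxonomy node
#'
#' Walks parent pointers from the query node to the root.
#'
#' @param db A `ref_db` (or bare taxonomy tibble).
#' @param taxid Query taxid.
#' @return Tibble of taxonomy nodes ordered from the query node (first row)
#'   to the root (last row).
#' @export
lineage <- function(db, taxid) {
  taxonomy <- if (inherits(db, "ref_db")) db$taxonomy else validate_taxonomy(db)
  if (!taxid %in% taxonomy$taxid) stop("unknown taxid: ", taxid, call. = FALSE)
  idx <- stats::setNames(seq_len(nrow(taxonomy)), taxonomy$taxid)
  path <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    path <- c(path, cur)
    parent <- taxonomy$parent_taxid[idx[[as.character(cur)]]]
    if (parent == cur) break
    cur <- parent
    if (length(path) > nrow(taxonomy)) stop("taxonomy contains a cycle", call. = FALSE)
  }
  taxonomy[idx[as.character(path)], , drop = FALSE]
}

#' Lowest common taxonomic rank of a set of taxa
#'
#' Finds the deepest taxonomy node shared by all lineages and reports its
#' rank, collapsed to one of `species`, `genus`, `family` or `higher`.
#'
#' @param db A `ref_db` (or taxonomy tibble).
#' @param taxids Vector of taxids (duplicates allowed; order irrelevant).
#' @return A single rank label.
#' @export
lowest_common_rank <- function(db, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) stop("empty taxid set", call. = FALSE)
  paths <- lapply(taxids, function(t) rev(lineage(db, t)$taxid))
  shared_depth <- 0L
  maxd <- min(lengths(paths))
  for (d in seq_len(maxd)) {
    vals <- vapply(paths, `[[`, integer(1), d)
    if (length(unique(vals)) == 1L) shared_depth <- d else break
  }
  if (shared_depth == 0L) return("higher")
  node <- paths[[1]][shared_depth]
  taxonomy <- if (inherits(db, "ref_db")) db$taxonomy else db
  rank <- taxonomy$rank[match(node, taxonomy$taxid)]
  if (rank %in% c("species", "genus", "family")) rank else "higher"
}

# Genus-level ancestor taxid of a node (NA if none on the lineage).
.genus_of <- function(db, taxid) {
  lin <- lineage(db, taxid)
  g <- lin$taxid[lin$rank == "genus"]
  if (length(g) == 0) NA_integer_ else g[[1]]
}

#' Target taxa of a reference database
#'
#' The unit "taxon" counted by the coverage and specificity indices: every
#' species represented by at least one record, plus every genus that has
#' genus-level records but no species-level record under it (a "unique
#' genus"). Records identified only to family rank or above contribute no
#' unit (they are still scanned during amplification).
#'
#' @param db A `ref_db`.
#' @return Tibble with columns `key_taxid`, `rank_of_key` (`species` or
#'   `genus`) and `name`, one row per taxon unit.
#' @export
target_taxa <- function(db) {
  taxonomy <- db$taxonomy
  rec_tax <- unique(db$records$taxid)
  ranks <- taxonomy$rank[match(rec_tax, taxonomy$taxid)]
  species_keys <- rec_tax[ranks == "species"]
  species_genera <- unique(stats::na.omit(
    vapply(species_keys, function(t) .genus_of(db, t), integer(1))
  ))
  genus_records <- rec_tax[ranks == "genus"]
  genus_keys <- setdiff(genus_records, species_genera)
  keys <- tibble::tibble(
    key_taxid = c(sort(species_keys), sort(genus_keys)),
    rank_of_key = c(rep("species", length(species_keys)),
                    rep("genus", length(genus_keys)))
  )
  keys$name <- taxonomy$name[match(keys$key_taxid, taxonomy$taxid)]
  keys
}

# Map each record to its taxon-unit key (NA when the record belongs to no
# unit: family-or-above annotation, or a genus-level record whose genus is
# already represented by species records).
.record_units <- function(db) {
  tt <- target_taxa(db)
  ranks <- db$taxonomy$rank[match(db$records$taxid, db$taxonomy$taxid)]
  unit <- ifelse(db$records$taxid %in% tt$key_taxid, db$records$taxid, NA_integer_)
  dplyr::mutate(db$records[, c("record_id", "taxid")],
                rank = ranks, unit_taxid = as.integer(unit))
}
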