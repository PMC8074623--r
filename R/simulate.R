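# Seeded generator of annotated reference databases with full ground truth:
# a three-level taxonomy, conserved primer-annealing flanks around a
# hypervariable insert, controlled per-taxon primer mismatches, planted
# ambiguous taxon pairs, truncated (missing-region) records and genus-only
# records.

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a curated rRNA reference
#' snapshot at desk scale: a three-level taxonomy, two records per species,
#' conserved primer flanks bordering a hypervariable insert of 131-196 bp,
#' roughly 8% of taxa carrying enough primer-site mismatches to escape an
#' exact-match amplification, 7% of taxa with truncated records lacking the
#' target region, about one genus-only taxon per ten species, and two
#' same-genus plus two same-family taxon pairs with identical inserts.
#'
#' @param seed Integer seed; all sampling flows through one seeded RNG.
#' @param n_families,n_genera_per_family,n_species_per_genus Taxonomy shape.
#' @param records_per_species Records per species taxon.
#' @param fraction_genus_only Number of extra genus-only taxa as a fraction
#'   of the species count (rounded).
#' @param flank_fwd,flank_rev Primer pair whose annealing sites flank the
#'   insert; `flank_rev` is the reverse primer 5' to 3' (its reverse
#'   complement is embedded downstream of the insert).
#' @param insert_length_range Integer pair: insert length bounds.
#' @param per_taxon_mismatch_distribution Named numeric vector mapping
#'   mismatch count to probability (must sum to 1). Mismatches are planted
#'   in the forward primer site, away from its 3' end.
#' @param n_ambiguous_pairs_same_genus,n_ambiguous_pairs_same_family Number
#'   of planted taxon pairs sharing an identical insert within one genus /
#'   across genera of one family.
#' @param fraction_missing_region Fraction of taxa whose records are
#'   truncated to omit the target region entirely.
#' @param substitution_rate_within_taxon Per-base substitution rate applied
#'   to pad regions (outside primer sites and insert) so records of one
#'   taxon differ without disturbing planted mismatch counts or insert
#'   identity.
#' @param gc_bias GC probability for random sequence.
#' @param pad_length Length of random padding on each side of the amplicon.
#' @param engine_max_mismatches Mismatch budget assumed when deriving the
#'   expected amplifiable set in the ground truth.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_families = 6, n_genera_per_family = 2,
                       n_species_per_genus = 3, records_per_species = 2,
                       fraction_genus_only = 0.10,
                       flank_fwd = "CGCGGCGCTACATATTAGAC",
                       flank_rev = "GCACTTAACCGACCGTCGAC",
                       insert_length_range = c(131L, 196L),
                       per_taxon_mismatch_distribution = c(`0` = 0.92, `4` = 0.08),
                       n_ambiguous_pairs_same_genus = 2,
                       n_ambiguous_pairs_same_family = 2,
                       fraction_missing_region = 0.07,
                       substitution_rate_within_taxon = 0.02,
                       gc_bias = 0.5,
                       pad_length = 80L,
                       engine_max_mismatches = 0) {
  p <- per_taxon_mismatch_distribution
  if (abs(sum(p) - 1) > 1e-8) stop("mismatch distribution must sum to 1", call. = FALSE)
  stopifnot(fraction_genus_only >= 0, fraction_genus_only <= 1,
            fraction_missing_region >= 0, fraction_missing_region <= 1,
            insert_length_range[1] <= insert_length_range[2])
  structure(list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    n_genera_per_family = as.integer(n_genera_per_family),
    n_species_per_genus = as.integer(n_species_per_genus),
    records_per_species = as.integer(records_per_species),
    fraction_genus_only = fraction_genus_only,
    flank_fwd = normalize_sequence(flank_fwd),
    flank_rev = normalize_sequence(flank_rev),
    insert_length_range = as.integer(insert_length_range),
    per_taxon_mismatch_distribution = p,
    n_ambiguous_pairs_same_genus = as.integer(n_ambiguous_pairs_same_genus),
    n_ambiguous_pairs_same_family = as.integer(n_ambiguous_pairs_same_family),
    fraction_missing_region = fraction_missing_region,
    substitution_rate_within_taxon = substitution_rate_within_taxon,
    gc_bias = gc_bias,
    pad_length = as.integer(pad_length),
    engine_max_mismatches = as.integer(engine_max_mismatches)
  ), class = "sim_config")
}

# sample() resolves a length-1 numeric x as 1:x; always treat x as a set
.sample_set <- function(x, size) x[sample.int(length(x), size)]

.rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute `k` positions of `site`, restricted to the first `safe_len`
# positions (5' side), guaranteeing a base change at each.
.plant_mismatches <- function(site, k, safe_len) {
  if (k == 0) return(site)
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  safe_len <- min(safe_len, length(chars))
  if (k > safe_len) stop("more planted mismatches than safe primer positions",
                         call. = FALSE)
  pos <- .sample_set(seq_len(safe_len), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

.mutate_pad <- function(pad, rate) {
  if (rate <= 0 || nchar(pad) == 0) return(pad)
  chars <- strsplit(pad, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a reference database with ground truth
#'
#' Generates the taxonomy, annotated records, a flank-insert-flank
#' alignment for diversity profiling, and the planted ground truth
#' (amplifiable, identifiable, ambiguous, missing-region taxa and the
#' expected coverage/specificity indices under the configured engine
#' mismatch budget). Byte-identical output for identical seeds.
#'
#' @param config A [sim_config()].
#' @return A `ref_sim` list: `db` (a `ref_db`), `alignment` (named
#'   character vector), `truth` (list), `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(config$seed)

  n_species <- config$n_families * config$n_genera_per_family *
    config$n_species_per_genus
  n_genus_only <- round(config$fraction_genus_only * n_species)

  # taxonomy: root 1, families, genera (incl. genus-only), species
  tax <- list(tibble::tibble(taxid = 1L, parent_taxid = 1L,
                             rank = "no_rank", name = "root"))
  next_id <- 2L
  fam_ids <- integer(config$n_families)
  for (f in seq_len(config$n_families)) {
    fam_ids[f] <- next_id
    tax <- c(tax, list(tibble::tibble(taxid = next_id, parent_taxid = 1L,
                                      rank = "family",
                                      name = sprintf("Family_%02d", f))))
    next_id <- next_id + 1L
  }
  genus_parent <- integer(0); genus_ids <- integer(0)
  for (f in seq_len(config$n_families)) {
    for (g in seq_len(config$n_genera_per_family)) {
      genus_ids <- c(genus_ids, next_id)
      genus_parent <- c(genus_parent, fam_ids[f])
      tax <- c(tax, list(tibble::tibble(taxid = next_id,
                                        parent_taxid = fam_ids[f],
                                        rank = "genus",
                                        name = sprintf("Genus_%02d_%02d", f, g))))
      next_id <- next_id + 1L
    }
  }
  species <- tibble::tibble(taxid = integer(0), genus = integer(0),
                            family = integer(0))
  for (gi in seq_along(genus_ids)) {
    for (s in seq_len(config$n_species_per_genus)) {
      species <- dplyr::add_row(species, taxid = next_id,
                                genus = genus_ids[gi],
                                family = genus_parent[gi])
      tax <- c(tax, list(tibble::tibble(taxid = next_id,
                                        parent_taxid = genus_ids[gi],
                                        rank = "species",
                                        name = sprintf("Species_%04d", next_id))))
      next_id <- next_id + 1L
    }
  }
  genus_only <- tibble::tibble(taxid = integer(0), family = integer(0))
  if (n_genus_only > 0) {
    fam_cycle <- rep(fam_ids, length.out = n_genus_only)
    for (k in seq_len(n_genus_only)) {
      genus_only <- dplyr::add_row(genus_only, taxid = next_id,
                                   family = fam_cycle[k])
      tax <- c(tax, list(tibble::tibble(taxid = next_id,
                                        parent_taxid = fam_cycle[k],
                                        rank = "genus",
                                        name = sprintf("GenusOnly_%02d", k))))
      next_id <- next_id + 1L
    }
  }
  taxonomy <- dplyr::bind_rows(tax)

  units <- tibble::tibble(
    taxid = c(species$taxid, genus_only$taxid),
    genus = c(species$genus, genus_only$taxid),
    family = c(species$family, genus_only$family),
    rank = c(rep("species", nrow(species)), rep("genus", nrow(genus_only)))
  )
  n_units <- nrow(units)

  # planted ambiguity pairs: same-genus pairs among species of one genus,
  # same-family pairs across genera of one family
  ambiguous_pairs <- list()
  used <- integer(0)
  if (config$n_ambiguous_pairs_same_genus > 0) {
    if (config$n_species_per_genus < 2) stop("infeasible config: same-genus pairs need >= 2 species per genus",
                                             call. = FALSE)
    gpool <- sample(unique(species$genus))
    if (length(gpool) < config$n_ambiguous_pairs_same_genus) {
      stop("infeasible config: more same-genus ambiguous pairs than genera",
           call. = FALSE)
    }
    for (k in seq_len(config$n_ambiguous_pairs_same_genus)) {
      cand <- setdiff(species$taxid[species$genus == gpool[k]], used)
      if (length(cand) < 2) stop("infeasible config: not enough free species for ambiguity",
                                 call. = FALSE)
      pr <- sort(.sample_set(cand, 2))
      ambiguous_pairs <- c(ambiguous_pairs,
                           list(list(taxids = pr, shared_rank = "genus")))
      used <- c(used, pr)
    }
  }
  if (config$n_ambiguous_pairs_same_family > 0) {
    if (config$n_genera_per_family < 2) stop("infeasible config: same-family pairs need >= 2 genera per family",
                                             call. = FALSE)
    fpool <- sample(fam_ids)
    if (length(fpool) < config$n_ambiguous_pairs_same_family) {
      stop("infeasible config: more same-family ambiguous pairs than families",
           call. = FALSE)
    }
    for (k in seq_len(config$n_ambiguous_pairs_same_family)) {
      fam_species <- species[species$family == fpool[k] &
                               !species$taxid %in% used, , drop = FALSE]
      genera_here <- unique(fam_species$genus)
      if (length(genera_here) < 2) stop("infeasible config: not enough free genera for family-level ambiguity",
                                        call. = FALSE)
      g2 <- .sample_set(genera_here, 2)
      a <- .sample_set(fam_species$taxid[fam_species$genus == g2[1]], 1)
      b <- .sample_set(fam_species$taxid[fam_species$genus == g2[2]], 1)
      pr <- sort(c(a, b))
      ambiguous_pairs <- c(ambiguous_pairs,
                           list(list(taxids = pr, shared_rank = "family")))
      used <- c(used, pr)
    }
  }
  ambiguous_members <- sort(unique(unlist(lapply(ambiguous_pairs, `[[`, "taxids"))))

  # per-taxon assignments: missing region, mismatch count, insert
  free <- setdiff(units$taxid, ambiguous_members)
  n_missing <- round(config$fraction_missing_region * n_units)
  if (n_missing > length(free)) stop("infeasible config: too many missing-region taxa",
                                     call. = FALSE)
  missing_taxa <- sort(.sample_set(free, n_missing))

  mm_counts <- as.integer(names(config$per_taxon_mismatch_distribution))
  mm_of <- stats::setNames(rep(0L, n_units), units$taxid)
  samplable <- setdiff(free, missing_taxa)
  mm_of[as.character(samplable)] <- sample(
    mm_counts, length(samplable), replace = TRUE,
    prob = config$per_taxon_mismatch_distribution
  )

  lf <- nchar(config$flank_fwd)
  safe_len <- lf - max(3L, config$engine_max_mismatches)  # keep 3' end intact
  ins_range <- config$insert_length_range
  insert_of <- stats::setNames(character(n_units), units$taxid)
  for (i in seq_len(n_units)) {
    insert_of[[as.character(units$taxid[i])]] <-
      .rand_seq(.sample_set(seq.int(ins_range[1], ins_range[2]), 1), config$gc_bias)
  }
  for (pr in ambiguous_pairs) {
    insert_of[[as.character(pr$taxids[2])]] <- insert_of[[as.character(pr$taxids[1])]]
  }

  rev_site <- revcomp(config$flank_rev)
  records <- list()
  for (i in seq_len(n_units)) {
    tid <- units$taxid[i]
    n_rec <- if (units$rank[i] == "species") config$records_per_species else 1L
    missing <- tid %in% missing_taxa
    fwd_site <- .plant_mismatches(config$flank_fwd, mm_of[[as.character(tid)]],
                                  safe_len)
    for (r in seq_len(n_rec)) {
      pad5 <- .rand_seq(config$pad_length, config$gc_bias)
      pad3 <- .rand_seq(config$pad_length, config$gc_bias)
      if (missing) {
        seq <- paste0(.mutate_pad(pad5, config$substitution_rate_within_taxon),
                      .mutate_pad(pad3, config$substitution_rate_within_taxon))
      } else {
        seq <- paste0(.mutate_pad(pad5, config$substitution_rate_within_taxon),
                      fwd_site, insert_of[[as.character(tid)]], rev_site,
                      .mutate_pad(pad3, config$substitution_rate_within_taxon))
      }
      records <- c(records, list(tibble::tibble(
        record_id = sprintf("SIM%06d_%d", tid, r),
        sequence = seq, taxid = tid
      )))
    }
  }
  records <- dplyr::bind_rows(records)

  db <- new_ref_db(records, taxonomy,
                   report = list(n_loaded = nrow(records), n_dropped = 0L,
                                 dropped_records = character(0)))

  # alignment of full amplicons (flank + gap-padded insert + flank) for the
  # diversity profile; one amplifiable record per taxon
  amp_taxa <- setdiff(units$taxid, missing_taxa)
  ins <- insert_of[as.character(amp_taxa)]
  wmax <- max(nchar(ins))
  aligned <- vapply(seq_along(amp_taxa), function(i) {
    paste0(config$flank_fwd,
           ins[i], strrep("-", wmax - nchar(ins[i])),
           rev_site)
  }, character(1))
  names(aligned) <- sprintf("SIM%06d_1", amp_taxa)

  budget <- config$engine_max_mismatches
  amplifiable <- sort(units$taxid[!units$taxid %in% missing_taxa &
                                    mm_of[as.character(units$taxid)] <= budget])
  identifiable <- sort(setdiff(amplifiable, ambiguous_members))
  truth <- list(
    target_taxa = sort(units$taxid),
    amplifiable = amplifiable,
    identifiable = identifiable,
    ambiguous_pairs = ambiguous_pairs,
    missing_region = missing_taxa,
    region_present_unamplified = sort(setdiff(units$taxid,
                                              c(missing_taxa, amplifiable))),
    mismatches = mm_of,
    expected_bc = coverage_index(length(amplifiable), n_units),
    expected_bs = specificity_index(length(identifiable), length(amplifiable)),
    expected_bc_raw = length(amplifiable) / n_units,
    expected_bs_raw = length(identifiable) / length(amplifiable)
  )
  structure(list(db = db, alignment = aligned, truth = truth, config = config),
            class = "ref_sim")
}

#' @export
print.ref_sim <- function(x, ...) {
  cat(sprintf("<ref_sim> seed %d: %d records, %d target taxa (expected Bc %.2f, Bs %.2f)\n",
              x$config$seed, nrow(x$db$records), length(x$truth$target_taxa),
              x$truth$expected_bc, x$truth$expected_bs))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes the annotated FASTA (headers carry `taxid=<int>;`), the taxonomy
#' TSV, the aligned FASTA and the ground-truth JSON.
#'
#' @param sim A `ref_sim` from [simulate_reference()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ref_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fasta"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    alignment = file.path(dir, "alignment.fasta"),
    truth = file.path(dir, "ground_truth.json")
  )
  seqs <- Biostrings::BStringSet(sim$db$records$sequence)
  names(seqs) <- sprintf("%s taxid=%d;", sim$db$records$record_id,
                         sim$db$records$taxid)
  .write_atomic(function(tmp) Biostrings::writeXStringSet(seqs, tmp), paths["fasta"])
  .write_atomic(function(tmp) {
    utils::write.table(sim$db$taxonomy, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, paths["taxonomy"])
  aln <- Biostrings::BStringSet(sim$alignment)
  names(aln) <- names(sim$alignment)
  .write_atomic(function(tmp) Biostrings::writeXStringSet(aln, tmp), paths["alignment"])
  truth <- sim$truth
  truth$ambiguous_pairs <- lapply(truth$ambiguous_pairs, function(p) {
    list(taxids = p$taxids, shared_rank = p$shared_rank)
  })
  truth$mismatches <- as.list(truth$mismatches)
  .write_atomic(function(tmp) {
    jsonlite::write_json(truth, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, paths["truth"])
  paths
}
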