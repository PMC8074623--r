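# Reference-database model: loading, lineage resolution and the taxon-unit
# definition.

test_that("load_reference parses annotated FASTA and drops unresolvable taxids", {
  db0 <- tiny_db()
  files <- write_db_files(db0)
  db <- load_reference(files$fasta, files$tax)
  expect_s3_class(db, "ref_db")
  expect_equal(nrow(db$records), 4)
  expect_equal(sort(db$records$taxid), c(30L, 31L, 32L, 33L))
  expect_equal(db$records$length_bp, nchar(db$records$sequence))
  expect_equal(db$report$n_dropped, 0)

  # a record with a taxid absent from the taxonomy is dropped and counted
  cat(sprintf(">orphan taxid=999;\n%s\n", random_dna(80)),
      file = files$fasta, append = TRUE)
  db2 <- load_reference(files$fasta, files$tax)
  expect_equal(nrow(db2$records), 4)
  expect_equal(db2$report$n_dropped, 1)
  expect_equal(db2$report$dropped_records, "orphan")
})

test_that("load_reference normalizes alphabet and accepts a sidecar taxid map", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "mix.fasta")
  writeLines(c(">rna1 taxid=30;", "acgu-ug..ca", ">plain2", "AACCGGTT"), fasta)
  tax <- file.path(dir, "tax.tsv")
  utils::write.table(tiny_taxonomy(), tax, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map <- file.path(dir, "map.tsv")
  writeLines("plain2\t31", map)
  db <- load_reference(fasta, tax, taxid_map_path = map)
  expect_equal(db$records$sequence[db$records$record_id == "rna1"], "ACGTTGCA")
  expect_equal(db$records$taxid[db$records$record_id == "plain2"], 31L)
})

test_that("loader and taxonomy validation reject malformed input", {
  files <- write_db_files(tiny_db())
  expect_error(load_reference(file.path(files$dir, "nope.fasta"), files$tax),
               "not found")
  bad <- tiny_taxonomy()
  bad$parent_taxid[bad$taxid == 20L] <- 999L
  expect_error(validate_taxonomy(bad), "parent")
  bad2 <- tiny_taxonomy()
  bad2$rank[2] <- "phylum"
  expect_error(validate_taxonomy(bad2), "rank")
  expect_error(validate_taxonomy(tiny_taxonomy()[-1, ]), "root")
})

test_that("lineage walks to the root and round-trips the parent table", {
  db <- tiny_db()
  root <- lineage(db, 1L)
  expect_equal(nrow(root), 1)
  expect_equal(root$taxid, 1L)

  lin <- lineage(db, 30L)
  expect_equal(lin$taxid, c(30L, 20L, 10L, 1L))
  expect_equal(lin$rank, c("species", "genus", "family", "no_rank"))

  # sibling species share all but the first lineage element
  a <- lineage(db, 30L); b <- lineage(db, 31L)
  expect_equal(a$taxid[-1], b$taxid[-1])

  # round-trip: consecutive lineage elements reproduce parent pointers
  for (t in db$taxonomy$taxid) {
    lin <- lineage(db, t)
    if (nrow(lin) > 1) {
      expect_equal(lin$taxid[-1],
                   db$taxonomy$parent_taxid[match(lin$taxid[-nrow(lin)],
                                                  db$taxonomy$taxid)])
    }
  }
  expect_error(lineage(db, 777L), "unknown taxid")
})

test_that("lowest_common_rank resolves shared depth and ignores order/duplication", {
  db <- tiny_db()
  expect_equal(lowest_common_rank(db, 30L), "species")
  expect_equal(lowest_common_rank(db, c(30L, 31L)), "genus")
  expect_equal(lowest_common_rank(db, c(30L, 32L)), "family")
  expect_equal(lowest_common_rank(db, c(30L, 33L)), "higher")
  expect_equal(lowest_common_rank(db, c(31L, 30L)), "genus")
  expect_equal(lowest_common_rank(db, c(30L, 30L, 31L, 31L)), "genus")
  expect_error(lowest_common_rank(db, integer(0)), "empty")
})

test_that("target_taxa counts species plus unique genera only", {
  db <- tiny_db()
  tt <- target_taxa(db)
  expect_equal(sort(tt$key_taxid), c(30L, 31L, 32L, 33L))
  expect_true(all(tt$rank_of_key == "species"))

  # genus-only record whose genus lacks species records adds a genus unit;
  # one whose genus has species records folds into no new unit
  recs <- dplyr::bind_rows(
    db$records,
    tibble::tibble(record_id = "g20", sequence = random_dna(60), taxid = 20L),
    tibble::tibble(record_id = "g21b", sequence = random_dna(60), taxid = 21L)
  )
  # remove the only species of genus 21 so that genus becomes "unique"
  recs <- recs[recs$record_id != "r32", ]
  db2 <- new_ref_db(recs, tiny_taxonomy())
  tt2 <- target_taxa(db2)
  expect_setequal(tt2$key_taxid, c(30L, 31L, 33L, 21L))
  expect_equal(tt2$rank_of_key[tt2$key_taxid == 21L], "genus")
  # |target_taxa| never exceeds distinct record taxids
  expect_lte(nrow(tt2), length(unique(db2$records$taxid)))
})

test_that("generator fixture yields the planted record and taxon counts", {
  sim <- simulate_reference(sim_config(
    seed = 1, n_families = 5, n_genera_per_family = 1,
    n_species_per_genus = 2, records_per_species = 2,
    fraction_genus_only = 0, fraction_missing_region = 0,
    n_ambiguous_pairs_same_genus = 0, n_ambiguous_pairs_same_family = 0
  ))
  expect_equal(nrow(sim$db$records), 20)
  tt <- target_taxa(sim$db)
  expect_equal(nrow(tt), 10)
  expect_true(all(tt$rank_of_key == "species"))
})

test_that("read_taxdump converts NCBI-style dump files", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.dmp")
  names_f <- file.path(dir, "names.dmp")
  writeLines(c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tfamily\t|",
    "3\t|\t2\t|\tgenus\t|",
    "4\t|\t3\t|\tspecies\t|"
  ), nodes)
  writeLines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tSepiidae\t|\t\t|\tscientific name\t|",
    "2\t|\tcuttlefishes\t|\t\t|\tcommon name\t|",
    "3\t|\tSepia\t|\t\t|\tscientific name\t|",
    "4\t|\tSepia elegans\t|\t\t|\tscientific name\t|"
  ), names_f)
  tax <- read_taxdump(nodes, names_f)
  expect_equal(nrow(tax), 4)
  expect_equal(tax$rank, c("no_rank", "family", "genus", "species"))
  expect_equal(tax$name[tax$taxid == 4L], "Sepia elegans")
  db <- new_ref_db(
    tibble::tibble(record_id = "x", sequence = random_dna(50), taxid = 4L),
    tax
  )
  expect_equal(lineage(db, 4L)$taxid, c(4L, 3L, 2L, 1L))
})

test_that("write_load_report emits the load counts as JSON", {
  files <- write_db_files(tiny_db())
  db <- load_reference(files$fasta, files$tax)
  path <- file.path(files$dir, "report.json")
  write_load_report(db, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$n_records, 4)
  expect_equal(rep$n_taxa, 4)
  expect_equal(rep$n_dropped, 0)
})
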