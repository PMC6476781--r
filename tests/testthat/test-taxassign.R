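fixture_reference <- function() {
  withr::with_seed(31, {
    seqs <- tibble::tibble(
      ref_id = sprintf("ref_%02d", 1:4),
      seq = vapply(1:4, function(i) olspr:::random_dna(150), character(1)))
    taxonomy <- tibble::tibble(
      ref_id = seqs$ref_id,
      kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
      order = c("Ephemeroptera", "Ephemeroptera", "Diptera", "Trichoptera"),
      family = c("Baetidae", "Baetidae", "Chironomidae", "Hydropsychidae"),
      genus = c("Baetis", "Cloeon", "Chironomus", "Hydropsyche"),
      species = c("Baetis fuscatus", "Cloeon dipterum",
                  "Chironomus riparius", "Hydropsyche modesta"))
    list(seqs = seqs, taxonomy = taxonomy)
  })
}

test_that("reference search reports identity from pairwise alignment", {
  ref <- fixture_reference()
  hits <- search_reference(ref$seqs$seq[1], ref)
  expect_equal(hits$ref_id, "ref_01")
  expect_equal(hits$identity, 100)

  # two interior mismatches on a 150-mer: ~98.7% identity
  q <- ref$seqs$seq[1]
  for (i in c(60, 90)) {
    substr(q, i, i) <- setdiff(c("A", "C", "G", "T"), substr(q, i, i))[1]
  }
  hits <- search_reference(q, ref)
  expect_equal(hits$ref_id, "ref_01")
  expect_equal(hits$identity, 100 * 148 / 150, tolerance = 1e-6)

  # a sequence unrelated to every reference returns no hits
  expect_equal(nrow(search_reference(strrep("ACGT", 40), ref)), 0L)
})

make_hits <- function(identity, species, genus, family = "Baetidae",
                      order = "Ephemeroptera") {
  tibble::tibble(
    ref_id = sprintf("h%02d", seq_along(identity)), identity = identity,
    kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
    order = order, family = family, genus = genus, species = species)
}

test_that("lowest-taxonomic-group assignment follows band, fraction and cap rules", {
  # all hits one species at >= 97%: species-level call
  h <- make_hits(c(99, 98.5), rep("Baetis fuscatus", 2), rep("Baetis", 2))
  a <- ltg_assign(h)
  expect_equal(a$resolution_rank, "species")
  expect_equal(a$species, "Baetis fuscatus")

  # 50/50 split across two genera of one family: family by the fraction rule
  h <- make_hits(c(99, 98), c("Baetis fuscatus", "Cloeon dipterum"),
                 c("Baetis", "Cloeon"))
  a <- ltg_assign(h)
  expect_equal(a$resolution_rank, "family")
  expect_equal(a$family, "Baetidae")
  expect_true(is.na(a$genus) && is.na(a$species))

  # hits only at 91%, all one genus: the band cap limits the call to family
  h <- make_hits(c(91, 90.5), rep("Baetis fuscatus", 2), rep("Baetis", 2))
  a <- ltg_assign(h)
  expect_equal(a$resolution_rank, "family")

  # the top band wins even when lower bands have more hits
  h <- make_hits(c(97.5, 84, 84, 84), c("Baetis fuscatus", rep("Cloeon dipterum", 3)),
                 c("Baetis", rep("Cloeon", 3)))
  a <- ltg_assign(h)
  expect_equal(a$species, "Baetis fuscatus")

  # empty hit list: unassigned, rank score 0
  a <- ltg_assign(make_hits(numeric(0), character(0), character(0)))
  expect_true(is.na(a$resolution_rank))
  expect_equal(ir_score(a$resolution_rank), 0L)
})

test_that("adding hits of the chosen taxon never coarsens the assignment", {
  h <- make_hits(c(99, 98), rep("Baetis fuscatus", 2), rep("Baetis", 2))
  base_rank <- ltg_assign(h)$resolution_rank
  h_more <- dplyr::bind_rows(h, make_hits(98.7, "Baetis fuscatus", "Baetis"))
  expect_equal(ltg_assign(h_more)$resolution_rank, base_rank)
})

test_that("the IR scale maps ranks to 0..6", {
  expect_equal(ir_score(c("species", "genus", "family", "order", "class",
                          "phylum", "kingdom", NA)),
               c(6L, 5L, 4L, 3L, 2L, 1L, 0L, 0L))
  expect_equal(sample_ir(rep("species", 4)), 6)
  expect_equal(sample_ir(c("species", "genus")), 5.5)
  expect_equal(sample_ir(NA_character_), 0)
  expect_true(is.na(sample_ir(character(0))))
})

test_that("the Macrometazoan scope filter excludes by any rank on the path", {
  asg <- tibble::tibble(
    item_id = c("i1", "i2", "i3"),
    kingdom = "Animalia", phylum = c("Rotifera", "Arthropoda", NA),
    class = c(NA, "Insecta", NA), order = c(NA, "Ephemeroptera", NA),
    family = NA_character_, genus = NA_character_,
    species = NA_character_,
    resolution_rank = c("phylum", "order", NA))
  out <- filter_macrometazoa(asg)
  expect_setequal(out$item_id, c("i2", "i3"))
  expect_equal(out$unassigned_kept[out$item_id == "i3"], TRUE)
  expect_equal(out$unassigned_kept[out$item_id == "i2"], FALSE)
})

test_that("curated overrides supersede automatic assignments", {
  ref <- fixture_reference()
  items <- tibble::tibble(item_id = "x1", seq = ref$seqs$seq[1])
  ov <- tibble::tibble(item_id = "x1", kingdom = "Animalia",
                       phylum = "Arthropoda", class = "Insecta",
                       order = "Ephemeroptera", family = "Baetidae",
                       genus = "Baetis", species = "Baetis rhodani",
                       resolution_rank = "species")
  out <- assign_taxa(items, ref, overrides = ov)
  expect_equal(out$species, "Baetis rhodani")
  expect_equal(out$method, "override")
  expect_equal(out$ir, 6L)
})
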