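#' Configuration for a synthetic metabarcoding run
#'
#' Bundles every knob of the synthetic-run generator. The defaults emulate
#' the study design the package targets: 3 markers x 3 PCR replicates per
#' sample (9 PCRs per sample), 12 forward x 8 reverse tags of 11-13 nt at
#' pairwise distance >= 3, two mock communities of seven prey taxa at 0.2
#' relative concentration plus the predator at 0.8, four kinds of negative
#' control, tag switching, PCR point substitutions, and primer-specific taxon
#' dropout. Sizes (number of simulated eDNA samples, reads per PCR, number
#' of reference taxa) are kept modest so a full run simulates in seconds.
#'
#' @param seed Integer seed; fixes every output bit-for-bit.
#' @param n_taxa Number of reference taxa (>= the 12 mock-community taxa).
#' @param n_edna Number of eDNA samples drawn from the packaged census
#'   (`NULL` = the full census of 107).
#' @param n_replicates PCR replicates per sample and marker (default 3).
#' @param reads_per_pcr Reads emitted per eDNA/mock PCR.
#' @param substitution_rate Per-base PCR/sequencing substitution rate.
#' @param tag_switch_rate Per-read probability that one tag is replaced by a
#'   random tag of the same set (tag jump).
#' @param contam_rate Expected fraction of contamination reads in eDNA/mock
#'   PCRs.
#' @param neg_contam_mean Expected contamination reads per negative-control
#'   PCR.
#' @param marker_success Named per-marker probability that a taxon carries a
#'   compatible binding site (primer-specific dropout); every taxon is
#'   guaranteed at least one compatible marker.
#' @param abundance_sdlog Log-normal sdlog of within-sample prey abundances.
#' @param prey_range Range (min, max) of prey taxa per eDNA sample.
#' @param n_contaminants Number of reference taxa reserved as cross-habitat
#'   contaminant sources.
#' @param core_length Length of the shared amplicon core (the cross-marker
#'   overlap; default 120).
#' @param markers Marker primer tibble (default [default_markers()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 24L, n_edna = 8L,
                       n_replicates = 3L, reads_per_pcr = 300L,
                       substitution_rate = 5e-4, tag_switch_rate = 1e-3,
                       contam_rate = 0.003, neg_contam_mean = 2,
                       marker_success = c(MFZR = 0.5, ZFZR = 0.7,
                                          LFCR = 0.64),
                       abundance_sdlog = 1, prey_range = c(3L, 8L),
                       n_contaminants = 2L, core_length = 120L,
                       markers = default_markers()) {
  stopifnot(n_taxa >= 12 + n_contaminants,
            substitution_rate >= 0, substitution_rate <= 1,
            tag_switch_rate >= 0, tag_switch_rate <= 1,
            all(marker_success >= 0), all(marker_success <= 1))
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one concrete ACGT realisation of an IUPAC pattern
realize_iupac <- function(pattern) {
  tab <- iupac_table()
  p <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(p, function(ch) {
    opts <- tab[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# corrupt `k` positions of `site` so it mismatches the IUPAC `pattern` there
plant_mismatches <- function(site, pattern, k) {
  tab <- iupac_table()
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(site, "")[[1]]
  pos <- sample(seq_along(s), k)
  for (i in pos) {
    bad <- setdiff(c("A", "C", "G", "T"), tab[[p[i]]])
    if (length(bad) == 0) bad <- setdiff(c("A", "C", "G", "T"), s[i])
    s[i] <- sample(bad, 1)
  }
  paste(s, collapse = "")
}

mock_taxonomy <- function() {
  tibble::tribble(
    ~species, ~phylum, ~class, ~order, ~family, ~genus,
    "Ephemerella ignita", "Arthropoda", "Insecta", "Ephemeroptera",
      "Ephemerellidae", "Ephemerella",
    "Hydropsyche modesta", "Arthropoda", "Insecta", "Trichoptera",
      "Hydropsychidae", "Hydropsyche",
    "Oligoneuriella rhenana", "Arthropoda", "Insecta", "Ephemeroptera",
      "Oligoneuriidae", "Oligoneuriella",
    "Eisenia andrei", "Annelida", "Clitellata", "Haplotaxida",
      "Lumbricidae", "Eisenia",
    "Chironomus riparius", "Arthropoda", "Insecta", "Diptera",
      "Chironomidae", "Chironomus",
    "Dinocras cephalotes", "Arthropoda", "Insecta", "Plecoptera",
      "Perlidae", "Dinocras",
    "Phoxinus cf. phoxinus", "Chordata", "Actinopterygii", "Cypriniformes",
      "Leuciscidae", "Phoxinus",
    "Hydropsyche instabilis", "Arthropoda", "Insecta", "Trichoptera",
      "Hydropsychidae", "Hydropsyche",
    "Gammarus pulex", "Arthropoda", "Malacostraca", "Amphipoda",
      "Gammaridae", "Gammarus",
    "Planorbarius corneus", "Mollusca", "Gastropoda", "Hygrophila",
      "Planorbidae", "Planorbarius",
    "Velia saulii", "Arthropoda", "Insecta", "Hemiptera",
      "Veliidae", "Velia",
    "Zingel asper", "Chordata", "Actinopterygii", "Perciformes",
      "Percidae", "Zingel"
  ) |> dplyr::mutate(kingdom = "Animalia")
}

#' Generate a synthetic reference database
#'
#' Builds COI-like template sequences (~300 nt) for `n_taxa` taxa, each
#' embedding binding sites for all three markers in a nested layout so that
#' the three amplicon windows overlap over a shared core. The 12
#' mock-community taxa are always included (freshwater habitat, complete
#' taxonomy to species); the remaining taxa get invented species names and
#' habitats, with `n_contaminants` of them assigned the marine habitat so
#' they are habitat-incompatible with every simulated sample and can serve
#' as planted contaminants. Per-taxon marker compatibility is drawn from
#' `marker_success` conditioned on at least one compatible marker;
#' incompatible binding sites carry three planted mismatches against the
#' primer, so they drop out at any demultiplexing tolerance below 3.
#'
#' @param config A [sim_config()].
#' @return A list: `seqs` (tibble `ref_id, seq`), `taxonomy`, `habitat`
#'   (tibble `taxon, habitat`), `amplicons` (tibble
#'   `ref_id, taxon, marker, compatible, amplicon, insert`), and
#'   `contaminants` (character).
#' @export
generate_reference <- function(config) {
  withr::with_seed(config$seed + 101L, {
    mk <- validate_markers(config$markers)
    mocks <- mock_taxonomy()
    n_other <- config$n_taxa - nrow(mocks)
    others <- tibble::tibble(
      species = sprintf("Simulotaxon sp%02d", seq_len(n_other)),
      phylum = "Arthropoda", class = "Insecta",
      order = sample(c("Diptera", "Ephemeroptera", "Trichoptera",
                       "Coleoptera", "Lepidoptera", "Hymenoptera"),
                     n_other, replace = TRUE),
      family = sprintf("Simulidae%02d", seq_len(n_other)),
      genus = sprintf("Simulotaxon%02d", seq_len(n_other)),
      kingdom = "Animalia")
    tax <- dplyr::bind_rows(mocks, others) |>
      dplyr::mutate(ref_id = sprintf("ref_%02d", dplyr::row_number()),
                    .before = 1)
    tax <- tax[c("ref_id", taxonomic_ranks())]

    n <- nrow(tax)
    contaminants <- tax$species[seq(n - config$n_contaminants + 1L, n)]
    habitat <- tibble::tibble(
      taxon = tax$species,
      habitat = c(rep("freshwater", nrow(mocks)),
                  sample(c("freshwater", "brackish", "terrestrial"),
                         n_other, replace = TRUE)))
    habitat$habitat[habitat$taxon %in% contaminants] <- "marine"

    # marker compatibility, conditioned on >= 1 compatible marker per taxon
    compat <- t(vapply(seq_len(n), function(i) {
      repeat {
        x <- stats::runif(nrow(mk)) < config$marker_success[mk$marker]
        if (any(x)) return(x)
      }
    }, logical(nrow(mk))))
    colnames(compat) <- mk$marker

    spacer <- function() random_dna(5L)
    rows <- purrr::map(seq_len(n), function(i) {
      f_sites <- stats::setNames(vapply(mk$fwd_primer, realize_iupac,
                                        character(1)), mk$marker)
      r_sites <- stats::setNames(vapply(mk$rev_primer, function(p) {
        revcomp(realize_iupac(p))   # top-strand binding site
      }, character(1)), mk$marker)
      for (m in mk$marker) {
        if (!compat[i, m]) {
          f_sites[m] <- plant_mismatches(f_sites[m],
                                         mk$fwd_primer[mk$marker == m], 3L)
        }
      }
      core <- random_dna(config$core_length)
      s1 <- spacer(); s2 <- spacer(); s3 <- spacer()
      template <- paste0(f_sites["MFZR"], s1, f_sites["ZFZR"], s2,
                         f_sites["LFCR"], core, r_sites["LFCR"], s3,
                         r_sites["MFZR"])
      inserts <- c(
        MFZR = paste0(s1, f_sites["ZFZR"], s2, f_sites["LFCR"], core,
                      r_sites["LFCR"], s3),
        ZFZR = paste0(s2, f_sites["LFCR"], core, r_sites["LFCR"], s3),
        LFCR = core)
      amplicons <- c(
        MFZR = paste0(f_sites["MFZR"], inserts["MFZR"], r_sites["MFZR"]),
        ZFZR = paste0(f_sites["ZFZR"], inserts["ZFZR"], r_sites["MFZR"]),
        LFCR = paste0(f_sites["LFCR"], inserts["LFCR"], r_sites["LFCR"]))
      list(template = template,
           amp = tibble::tibble(ref_id = tax$ref_id[i],
                                taxon = tax$species[i],
                                marker = mk$marker,
                                compatible = compat[i, mk$marker],
                                amplicon = unname(amplicons[mk$marker]),
                                insert = unname(inserts[mk$marker])))
    })

    list(seqs = tibble::tibble(ref_id = tax$ref_id,
                               seq = vapply(rows, function(x) x$template,
                                            character(1))),
         taxonomy = tax,
         habitat = habitat,
         amplicons = dplyr::bind_rows(purrr::map(rows, "amp")),
         contaminants = contaminants)
  })
}

#' Write a reference database to FASTA + taxonomy TSV
#' @param reference Result of [generate_reference()] or [read_reference()].
#' @param fasta,taxonomy Output paths.
#' @return `fasta`, invisibly.
#' @export
write_reference <- function(reference, fasta, taxonomy) {
  ss <- Biostrings::DNAStringSet(stats::setNames(reference$seqs$seq,
                                                 reference$seqs$ref_id))
  Biostrings::writeXStringSet(ss, fasta)
  readr::write_tsv(reference$taxonomy, taxonomy)
  invisible(fasta)
}

generate_tagset <- function(n, min_mismatches = 3L) {
  tags <- character(0)
  while (length(tags) < n) {
    cand <- random_dna(sample(11:13, 1))
    ok <- all(vapply(tags, function(t) {
      L <- min(nchar(t), nchar(cand))
      sum(strsplit(substr(t, 1, L), "")[[1]] !=
            strsplit(substr(cand, 1, L), "")[[1]]) >= min_mismatches
    }, logical(1)))
    if (ok) tags <- c(tags, cand)
  }
  tags
}

#' Generate a synthetic run design
#'
#' Emits 12 forward and 8 reverse tags (11-13 nt, pairwise distance >= 3, by
#' rejection sampling), draws `n_edna` eDNA samples from the packaged sample
#' census (or the full census when `n_edna = NULL`), and adds the two mock
#' communities plus one negative control of each of the four kinds to every
#' run. Samples are split across runs so each (run, marker) stays within the
#' 96 available tag combinations; tag pairs are assigned to PCRs by seeded
#' shuffling.
#'
#' @param config A [sim_config()].
#' @return An `olsp_design` with attributes `tags` (list with `fwd`, `rev`)
#'   and `mock_composition` (tibble `sample, taxon, weight, role`).
#' @export
generate_design <- function(config) {
  withr::with_seed(config$seed + 202L, {
    fwd_tags <- generate_tagset(12L)
    rev_tags <- generate_tagset(8L)
    census <- sample_census()
    pool <- census |>
      dplyr::mutate(idx = dplyr::row_number()) |>
      tidyr::uncount(.data$n_samples) |>
      dplyr::mutate(sample = sprintf("edna_%03d", dplyr::row_number()))
    if (!is.null(config$n_edna) && config$n_edna < nrow(pool)) {
      pool <- pool[sort(sample(nrow(pool), config$n_edna)), ]
      pool$sample <- sprintf("edna_%03d", seq_len(nrow(pool)))
    }
    edna <- dplyr::transmute(pool, sample = .data$sample, category = "edna",
                             predator = .data$predator_group,
                             habitat = .data$habitat)

    mock_comp_base <- mock_community()
    per_run <- max(1L, 96L %/% config$n_replicates - 6L)
    run_of <- ceiling(seq_len(nrow(edna)) / per_run)
    n_runs <- max(run_of)

    mock_rows <- list(); comp_rows <- list(); pcr_rows <- list()
    for (r in seq_len(n_runs)) {
      run_id <- sprintf("run%02d", r)
      suffix <- if (n_runs > 1) paste0("_", run_id) else ""
      controls <- tibble::tibble(
        sample = paste0(c("Tpos1", "Tpos2", "neg_ext", "neg_aer", "neg_pcr",
                          "neg_tag"), suffix),
        category = c("mock", "mock", negative_categories()),
        predator = NA_character_, habitat = NA_character_)
      comp_rows[[r]] <- mock_comp_base |>
        dplyr::transmute(sample = paste0(.data$mock, suffix),
                         taxon = .data$species,
                         weight = .data$concentration, role = .data$role)
      samples_r <- dplyr::bind_rows(edna[run_of == r, ], controls)
      grid <- tidyr::expand_grid(sample = samples_r$sample,
                                 replicate = seq_len(config$n_replicates))
      combos <- tidyr::expand_grid(fwd_tag = fwd_tags, rev_tag = rev_tags)
      if (nrow(grid) > nrow(combos)) {
        stop("too many PCRs per run for the available tag combinations")
      }
      pcr_rows[[r]] <- purrr::map(config$markers$marker, function(m) {
        pick <- combos[sample(nrow(combos), nrow(grid)), ]
        dplyr::bind_cols(grid, pick) |>
          dplyr::mutate(run = run_id, marker = m) |>
          dplyr::left_join(samples_r, by = "sample")
      }) |> dplyr::bind_rows()
    }
    design <- dplyr::bind_rows(pcr_rows)[design_columns()]
    out <- new_design(design, markers = config$markers)
    attr(out, "tags") <- list(fwd = fwd_tags, rev = rev_tags)
    attr(out, "mock_composition") <- dplyr::bind_rows(comp_rows)
    out
  })
}

# apply k substitutions to one read
substitute_bases <- function(seq, k) {
  pos <- sample(nchar(seq), k)
  s <- strsplit(seq, "")[[1]]
  for (i in pos) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

#' Simulate merged amplicon reads for a design
#'
#' For every PCR, draws a read composition (multinomial over the sample's
#' planted taxa, restricted to taxa whose binding sites are compatible with
#' the PCR's marker) and emits full tagged constructs
#' `fwd_tag + fwd site + insert + rev site + revcomp(rev_tag)`, about half of
#' them reverse-complemented. Mock PCRs follow the mock composition weights
#' (prey 0.2, predator 0.8); negative controls receive only contamination
#' reads. Point substitutions hit each base at `substitution_rate`; with
#' probability `tag_switch_rate` one of a read's tags is replaced by a random
#' tag of the same set (a tag jump). Contamination reads are drawn from the
#' reserved cross-habitat contaminant taxa.
#'
#' @param design From [generate_design()].
#' @param reference From [generate_reference()].
#' @param config The [sim_config()].
#' @return A list with `reads` (named character vector, names
#'   `read_xxxxxx run=...`-free; one entry per read), `run_of_read`
#'   (character vector of run ids), and `truth` (list: `composition` per-PCR
#'   taxon read counts, `provenance` per-read origin, `expected_items`
#'   per-sample taxa present in >= 2 replicates of >= 1 marker,
#'   `sample_taxa` planted per-sample taxon sets).
#' @export
simulate_reads <- function(design, reference, config) {
  withr::with_seed(config$seed + 303L, {
    mk <- config$markers
    amp <- reference$amplicons
    amp_key <- stats::setNames(amp$amplicon, paste(amp$taxon, amp$marker))
    compat_key <- stats::setNames(amp$compatible, paste(amp$taxon, amp$marker))
    mock_comp <- attr(design, "mock_composition")
    dtab <- tibble::as_tibble(design)
    fwd_tags <- attr(design, "tags")$fwd
    rev_tags <- attr(design, "tags")$rev
    if (is.null(fwd_tags)) {
      fwd_tags <- unique(dtab$fwd_tag); rev_tags <- unique(dtab$rev_tag)
    }

    samples <- dplyr::distinct(dtab, .data$sample, .data$category,
                               .data$habitat)
    # planted composition per sample (weights over taxa)
    sample_weights <- purrr::pmap(samples, function(sample, category,
                                                    habitat) {
      if (category == "mock") {
        comp <- mock_comp[mock_comp$sample == sample, ]
        tibble::tibble(sample = sample, taxon = comp$taxon,
                       weight = comp$weight)
      } else if (category == "edna") {
        pool <- reference$habitat$taxon[
          reference$habitat$habitat == habitat &
            !(reference$habitat$taxon %in% reference$contaminants)]
        k <- min(length(pool),
                 sample(config$prey_range[1]:config$prey_range[2], 1))
        taxa <- sample(pool, k)
        tibble::tibble(sample = sample, taxon = taxa,
                       weight = stats::rlnorm(k, 0, config$abundance_sdlog))
      } else {
        tibble::tibble(sample = sample, taxon = character(),
                       weight = numeric())
      }
    }) |> dplyr::bind_rows()

    pcrs <- dplyr::arrange(dtab, .data$run, .data$marker, .data$sample,
                           .data$replicate)
    comp_rows <- list(); read_rows <- list()
    for (i in seq_len(nrow(pcrs))) {
      p <- pcrs[i, ]
      w <- sample_weights[sample_weights$sample == p$sample, ]
      w <- w[compat_key[paste(w$taxon, p$marker)] %in% TRUE, ]
      counts <- integer(0)
      if (nrow(w) > 0 && p$category %in% c("edna", "mock")) {
        counts <- as.integer(stats::rmultinom(1, config$reads_per_pcr,
                                              w$weight))
        names(counts) <- w$taxon
      }
      n_cont <- stats::rpois(1, if (p$category %in% c("edna", "mock")) {
        config$contam_rate * config$reads_per_pcr
      } else config$neg_contam_mean)
      if (n_cont > 0) {
        pool <- reference$contaminants[
          compat_key[paste(reference$contaminants, p$marker)] %in% TRUE]
        if (length(pool) > 0) {
          src <- table(sample(pool, n_cont, replace = TRUE))
          for (t in names(src)) {
            counts[t] <- (if (t %in% names(counts)) counts[t] else 0L) +
              as.integer(src[t])
          }
        }
      }
      counts <- counts[counts > 0]
      if (length(counts) == 0) next
      comp_rows[[length(comp_rows) + 1]] <- tibble::tibble(
        run = p$run, marker = p$marker, sample = p$sample,
        category = p$category, replicate = p$replicate,
        taxon = names(counts), reads = as.integer(counts))
      read_rows[[length(read_rows) + 1]] <- tibble::tibble(
        run = p$run, marker = p$marker, sample = p$sample,
        replicate = p$replicate,
        taxon = rep(names(counts), counts),
        fwd_tag = p$fwd_tag, rev_tag = p$rev_tag)
    }
    reads_tbl <- dplyr::bind_rows(read_rows)
    n_reads <- nrow(reads_tbl)
    if (n_reads == 0) stop("simulation produced no reads")

    # tag switching
    switched <- stats::runif(n_reads) < config$tag_switch_rate
    for (i in which(switched)) {
      if (stats::runif(1) < 0.5) {
        reads_tbl$fwd_tag[i] <- sample(fwd_tags, 1)
      } else {
        reads_tbl$rev_tag[i] <- sample(rev_tags, 1)
      }
    }

    core <- amp_key[paste(reads_tbl$taxon, reads_tbl$marker)]
    seqs <- paste0(reads_tbl$fwd_tag, core, revcomp(reads_tbl$rev_tag))
    n_err <- if (config$substitution_rate > 0) {
      stats::rbinom(n_reads, nchar(seqs), config$substitution_rate)
    } else integer(n_reads)
    for (i in which(n_err > 0)) {
      seqs[i] <- substitute_bases(seqs[i], n_err[i])
    }
    flip <- stats::runif(n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    names(seqs) <- sprintf("read_%06d", seq_len(n_reads))

    provenance <- dplyr::mutate(
      reads_tbl, read_id = names(seqs), n_errors = n_err,
      switched = switched, flipped = flip)
    composition <- dplyr::bind_rows(comp_rows)

    expected_items <- composition |>
      dplyr::filter(.data$category %in% c("edna", "mock"),
                    !.data$taxon %in% reference$contaminants) |>
      dplyr::group_by(.data$sample, .data$marker, .data$taxon) |>
      dplyr::summarise(n_reps = dplyr::n_distinct(.data$replicate),
                       .groups = "drop") |>
      dplyr::filter(.data$n_reps >= 2) |>
      dplyr::distinct(.data$sample, .data$taxon)

    list(reads = seqs,
         run_of_read = stats::setNames(provenance$run, provenance$read_id),
         truth = list(composition = composition,
                      provenance = provenance,
                      expected_items = expected_items,
                      sample_taxa = sample_weights))
  })
}

#' Generate a complete synthetic run
#'
#' Convenience wrapper: reference, design, reads and ground truth from one
#' seeded configuration.
#' @param config A [sim_config()] (or arguments forwarded to it).
#' @param ... Arguments forwarded to [sim_config()] when `config` is missing.
#' @return A list with `config`, `reference`, `design`, `reads` (named list
#'   of read vectors, one per run) and `truth`.
#' @export
simulate_run <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  reference <- generate_reference(config)
  design <- generate_design(config)
  sim <- simulate_reads(design, reference, config)
  runs <- unique(tibble::as_tibble(design)$run)
  reads_by_run <- lapply(runs, function(r) sim$reads[sim$run_of_read == r])
  names(reads_by_run) <- runs
  list(config = config, reference = reference, design = design,
       reads = reads_by_run, truth = sim$truth)
}
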