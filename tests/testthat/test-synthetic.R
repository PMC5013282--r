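test_that("panel structure follows the genus layout", {
  cfg <- generator_config(seed = 2, n_genera = 5L, species_per_genus = 3L)
  pan <- generate_panel(cfg)
  ann <- pan$panel$annotations
  expect_equal(sum(ann$gene == "NS" & !ann$is_outgroup), 15)
  expect_equal(sum(ann$gene == "VP" & !ann$is_outgroup), 15)
  expect_equal(sum(ann$is_outgroup), 1)
  expect_equal(nrow(pan$panel$proteins), 31)
  # every NS (and the outgroup) contributes a reference SF3 fragment
  expect_equal(nrow(pan$sf3_refs), 16)
  expect_true(all(nchar(pan$sf3_refs$seq) == cfg$sf3_len))
})

test_that("intra-genus identity exceeds inter-genus identity in every genus", {
  cfg <- generator_config(seed = 3)
  pan <- generate_panel(cfg)
  ann <- pan$panel$annotations
  ns <- pan$panel$proteins[ann$gene == "NS" & !ann$is_outgroup, ]
  gen <- ann$genus[ann$gene == "NS" & !ann$is_outgroup]
  pid <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x == y)
  }
  for (g in unique(gen)) {
    own <- which(gen == g); other <- which(gen != g)
    intra <- mean(utils::combn(own, 2, function(ij)
      pid(ns$seq[ij[1]], ns$seq[ij[2]])))
    inter <- mean(vapply(own, function(i)
      mean(vapply(other, function(j) pid(ns$seq[i], ns$seq[j]), 0)), 0))
    expect_gt(intra, inter)
  }
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- generator_config(seed = 4, transcripts_per_host = 6L,
                          contig_len = 8000L, n_extant = 2L, n_intact = 1L,
                          n_degraded = 1L, n_contaminant = 1L, n_decoy = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_benchmark(generate_host_datasets(cfg, generate_panel(cfg)), d1)
  write_benchmark(generate_host_datasets(cfg, generate_panel(cfg)), d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
})

test_that("zero decay rates plant exact copies", {
  cfg <- generator_config(seed = 6, transcripts_per_host = 6L,
                          contig_len = 9000L, n_extant = 3L, n_intact = 0L,
                          n_degraded = 0L, n_contaminant = 0L, n_decoy = 0L,
                          extant_div = c(0, 0))
  pan <- generate_panel(cfg)
  bench <- generate_host_datasets(cfg, pan)
  expect_true(all(bench$truth$realized_aa_divergence == 0))
  expect_true(all(bench$truth$n_planted_stops == 0))
  for (i in seq_len(nrow(bench$truth))) {
    tr <- bench$truth[i, ]
    planted <- substr(
      bench$datasets[[tr$dataset_id]]$seq[
        bench$datasets[[tr$dataset_id]]$id == tr$target_id],
      tr$beg + 1, tr$end)
    expect_identical(planted, unname(pan$cds[tr$source_ref_id]))
  }
})

test_that("realized amino-acid divergence matches the mutation model", {
  # oracle: exact per-codon enumeration of the substitution model with
  # transition bias and stop rejection
  withr::local_seed(101)
  rate <- 0.12; kappa <- 4
  trans <- c(A = "G", G = "A", C = "T", T = "C")
  base_p <- function(from, to) {
    if (from == to) return(1 - rate)
    if (trans[[from]] == to) return(rate * kappa / (kappa + 2))
    rate / (kappa + 2)
  }
  stops <- c("TAA", "TAG", "TGA")
  expected_div <- function(cds) {
    nc <- nchar(cds) %/% 3
    p_tot <- 0
    for (k in seq_len(nc)) {
      cod <- substr(cds, 3 * k - 2, 3 * k)
      if (cod %in% stops) next
      aa0 <- ORACLE_CODE[[cod]]
      ch <- strsplit(cod, "")[[1]]
      for (b1 in NT4) for (b2 in NT4) for (b3 in NT4) {
        cod2 <- paste0(b1, b2, b3)
        if (cod2 %in% stops) next # stop-creating mutations are reverted
        p <- base_p(ch[1], b1) * base_p(ch[2], b2) * base_p(ch[3], b3)
        if (ORACLE_CODE[[cod2]] != aa0) p_tot <- p_tot + p
      }
    }
    p_tot / sum(!vapply(seq_len(nc), function(k)
      substr(cds, 3 * k - 2, 3 * k) %in% stops, TRUE))
  }
  cds <- rand_cds(rand_protein(150))
  want <- expected_div(cds)
  real <- replicate(60, parvoscreen:::aa_divergence(
    parvoscreen:::mutate_codons(cds, rate, kappa, TRUE), cds))
  expect_lt(abs(mean(real) - want) / want, 0.2)
})

test_that("stop planting follows the binomial model with rejection", {
  withr::local_seed(102)
  cds <- rand_cds(rand_protein(500), add_stop = TRUE)
  n <- replicate(200, parvoscreen:::plant_stops(cds, 0.02)$n_stops)
  expect_true(all(n >= 1))
  expect_lt(abs(mean(n) - 0.02 * (501 - 11)) / (0.02 * 490), 0.15)
  # rate zero: the deterministic re-draw rule forces exactly one stop
  none <- replicate(20, parvoscreen:::plant_stops(cds, 0)$n_stops)
  expect_true(all(none == 1))
})

test_that("expected labels derive from realized parameters and the rules", {
  cfg <- generator_config(seed = 8)
  pan <- generate_panel(cfg)
  ann <- pan$panel$annotations
  mam_ns <- ann$id[ann$gene == "NS" &
                     ann$host_lineage == "Metazoa;Chordata;Mammalia"][1]
  truth <- data.frame(
    event_id = c("e1", "e2", "e3"),
    event_type = c("EXTANT", "INTEGRATED_DEGRADED", "CONTAMINANT"),
    dataset_id = c("ant_tx", "ant_gn", "frog_tx"),
    target_id = "t", beg = 0L, end = 10L,
    source_ref_id = c(ann$id[1], ann$id[1], mam_ns),
    source_genus = "g",
    realized_aa_divergence = c(0.5, 0.3, 0.1),
    n_planted_stops = c(0L, 3L, 0L),
    frameshift_planted = FALSE, te_planted_5 = FALSE, te_planted_3 = FALSE,
    stringsAsFactors = FALSE)
  out <- expected_labels(truth, pan)
  expect_equal(out$expected_identity_bin,
               c("INTERMEDIATE", "INTERMEDIATE", "KNOWN_VIRUS_LIKE"))
  expect_equal(out$expected_origin,
               c("EXTANT_CANDIDATE", "ENDOGENOUS_DEGRADED",
                 "EXTANT_CANDIDATE"))
  expect_equal(out$expected_contaminant, c(FALSE, FALSE, TRUE))
})
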