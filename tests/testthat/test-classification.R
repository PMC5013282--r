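test_that("identity bins use exact inclusive-middle boundaries", {
  eps <- 1e-9
  expect_equal(identity_bin(0.30 - eps), "NOVEL_LINEAGE")
  expect_equal(identity_bin(0.30), "INTERMEDIATE")
  expect_equal(identity_bin(0.85), "INTERMEDIATE")
  expect_equal(identity_bin(0.85 + eps), "KNOWN_VIRUS_LIKE")
  expect_equal(identity_bin(c(0.29, 0.50, 0.86)),
               c("NOVEL_LINEAGE", "INTERMEDIATE", "KNOWN_VIRUS_LIKE"))
  expect_error(identity_bin(1.2), "\\[0, 1\\]")
  expect_error(identity_bin(-0.1), "\\[0, 1\\]")
})

ev_row <- function(n_match = 0, stops = NA, fs = NA, te5 = NA, te3 = NA,
                   intact = FALSE, edge = FALSE) {
  data.frame(prs_id = "p", n_genomic_matches = n_match,
             best_identity = NA_real_, internal_stop_count = stops,
             frameshift_suspected = fs, te_flank_5 = te5, te_flank_3 = te3,
             intact_ns_vp = intact, at_scaffold_edge = edge,
             stringsAsFactors = FALSE)
}

test_that("origin rules fire in priority order", {
  expect_equal(assign_origin(ev_row(1, stops = 2, te5 = TRUE))$origin,
               "ENDOGENOUS_DEGRADED")
  expect_equal(assign_origin(ev_row(1, stops = 0, fs = FALSE,
                                    intact = TRUE))$origin,
               "ENDOGENOUS_INTACT")
  expect_equal(assign_origin(ev_row(1, stops = 0, fs = FALSE))$origin,
               "AMBIGUOUS")
  expect_equal(assign_origin(ev_row(0))$origin, "EXTANT_CANDIDATE")
  # scaffold edge forces AMBIGUOUS unless degradation evidence fired
  expect_equal(assign_origin(ev_row(1, stops = 0, intact = TRUE,
                                    edge = TRUE))$origin, "AMBIGUOUS")
  expect_equal(assign_origin(ev_row(1, stops = 3, edge = TRUE))$origin,
               "ENDOGENOUS_DEGRADED")
  # degraded beats intact on mixed evidence
  expect_equal(assign_origin(ev_row(1, stops = 1, intact = TRUE))$origin,
               "ENDOGENOUS_DEGRADED")
})

test_that("contamination triage combines identity bin and lineage", {
  panel <- tiny_panel() # gA: insect-infecting; gB: mammal-infecting
  prs <- data.frame(prs_id = "p", recip_ref_id = "gB_sp1_NS",
                    stringsAsFactors = FALSE)
  plant <- "Viridiplantae;Streptophyta;Magnoliopsida;X_sp"
  frog <- "Metazoa;Chordata;Amphibia;X_sp"
  mouse <- "Metazoa;Chordata;Mammalia;X_sp"
  # plant dataset, high identity to an animal virus: suspect
  expect_true(contamination_triage(prs, "KNOWN_VIRUS_LIKE", panel, plant))
  # amphibian dataset vs mammal virus: same phylum, different class: suspect
  expect_true(contamination_triage(prs, "KNOWN_VIRUS_LIKE", panel, frog))
  # mammal dataset vs mammal virus: compatible
  expect_false(contamination_triage(prs, "KNOWN_VIRUS_LIKE", panel, mouse))
  # intermediate identity never triggers the rule
  expect_false(contamination_triage(prs, "INTERMEDIATE", panel, plant))
  # unevaluable lineage propagates as NA, not FALSE
  expect_true(is.na(contamination_triage(prs, "KNOWN_VIRUS_LIKE", panel,
                                         NA_character_)))
})

test_that("summaries count planted label mixtures exactly", {
  prs <- data.frame(
    prs_id = sprintf("PRS%02d", 1:10),
    dataset_id = rep(c("d1", "d2"), 5),
    gene_class = "NS",
    host_lineage = rep(c("Metazoa;Arthropoda;Insecta",
                         "Metazoa;Mollusca;Gastropoda"), 5),
    stringsAsFactors = FALSE)
  labels <- data.frame(
    prs_id = prs$prs_id,
    identity_bin = c(rep("INTERMEDIATE", 7), rep("KNOWN_VIRUS_LIKE", 3)),
    origin = c(rep("ENDOGENOUS_DEGRADED", 3), rep("ENDOGENOUS_INTACT", 2),
               rep("EXTANT_CANDIDATE", 5)),
    contaminant_suspect = c(rep(FALSE, 9), TRUE),
    rationale = "r", stringsAsFactors = FALSE)
  manifest <- data.frame(dataset_id = c("d1", "d2"), kind = "TRANSCRIPTOME",
                         host_lineage = unique(prs$host_lineage),
                         path = ".", stringsAsFactors = FALSE)
  s <- summarize_labels(labels, prs, manifest)
  expect_equal(s$by_origin$n[match(
    c("ENDOGENOUS_DEGRADED", "ENDOGENOUS_INTACT", "EXTANT_CANDIDATE"),
    s$by_origin$origin)], c(3, 2, 4)) # the contaminant is tabulated apart
  expect_equal(nrow(s$discarded), 1)
  expect_equal(sum(s$by_bin$proportion), 1, tolerance = 1e-9)
  expect_error(summarize_labels(transform(labels, prs_id = paste0(prs_id, "x")),
                                prs, manifest), "unknown prs_id")

  empty <- summarize_labels(labels[0, ], prs[0, ], manifest)
  expect_equal(nrow(empty$by_origin), 0)
  expect_equal(nrow(empty$discarded), 0)
})

test_that("classification is a pure function of its inputs", {
  bench <- small_benchmark(seed = 9)
  pan_bits <- list(panel = bench$panel)
  prs <- data.frame(prs_id = "PRS0001", dataset_id = bench$manifest$dataset_id[1],
                    host_lineage = bench$manifest$host_lineage[1],
                    target_id = "x", t_beg = 0L, t_end = 10L, strand = "+",
                    gene_class = "NS", fwd_evalue = 1e-9, fwd_score = 100L,
                    recip_evalue = 1e-8, recip_score = 90L,
                    recip_ref_id = bench$panel$proteins$id[1],
                    ref_genus = "genus01", best_reference_identity = 0.6,
                    seq = "ACGT", peptide = "MK", stringsAsFactors = FALSE)
  ev <- data.frame(prs_id = "PRS0001", n_genomic_matches = 0L,
                   best_identity = NA_real_,
                   internal_stop_count = NA_integer_,
                   frameshift_suspected = NA, te_flank_5 = NA,
                   te_flank_3 = NA, intact_ns_vp = FALSE,
                   at_scaffold_edge = FALSE, stringsAsFactors = FALSE)
  l1 <- classify_prs(prs, ev, bench$panel, bench$manifest)
  l2 <- classify_prs(prs, ev, bench$panel, bench$manifest)
  expect_identical(l1, l2)
  expect_equal(l1$origin, "EXTANT_CANDIDATE")
  expect_equal(l1$identity_bin, "INTERMEDIATE")
  expect_true(nzchar(l1$rationale))
})
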