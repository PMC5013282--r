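# A reusable planted-integration scene: one PRS sequence and a genome
# carrying a high-identity copy with controllable degradation and flanks.
make_scene <- function(seed, copy_mut = 0.02, stops = 0, frameshift = FALSE,
                       te_dist = NULL, te_len = 400, lead = 3000,
                       te_library = NULL) {
  withr::with_seed(seed, {
    panel <- tiny_panel()
    ns <- panel$proteins$seq[1]
    cds <- rand_cds(parvoscreen:::mutate_protein(ns, 0.15), add_stop = TRUE)
    prs_seq <- cds
    copy <- parvoscreen:::mutate_codons(cds, copy_mut, forbid_stops = TRUE)
    if (stops > 0) {
      ch <- strsplit(copy, "")[[1]]
      nc <- length(ch) %/% 3
      at <- round(seq(nc * 0.3, nc * 0.7, length.out = stops))
      for (k in at) ch[(3 * (k - 1) + 1):(3 * k)] <- c("T", "A", "A")
      copy <- paste(ch, collapse = "")
    }
    if (frameshift) {
      p <- nchar(copy) %/% 2
      copy <- paste0(substr(copy, 1, p), substr(copy, p + 2, nchar(copy)))
    }
    left <- if (is.null(te_dist)) rand_nt(lead) else {
      te <- te_library$seq[1] # TE ends te_dist nt before the element
      paste0(rand_nt(lead - nchar(te) - te_dist), te, rand_nt(te_dist))
    }
    contig <- paste0(left, copy, rand_nt(2000))
    genomes <- list(list(dataset_id = "gnA", host_lineage = "x;y",
                         targets = seq_set("ctg1", contig, moltype = "NT")))
    prs <- data.frame(prs_id = "PRS0001", dataset_id = "txA",
                      target_id = "tr1", t_beg = 0L,
                      t_end = nchar(prs_seq), strand = "+",
                      gene_class = "NS", recip_ref_id = panel$proteins$id[1],
                      seq = prs_seq, stringsAsFactors = FALSE)
    list(panel = panel, prs = prs, genomes = genomes,
         copy_beg = nchar(left), copy_end = nchar(left) + nchar(copy))
  })
}

test_that("genomic cross-referencing applies both cutoffs", {
  sc <- make_scene(71, copy_mut = 0.02)
  m <- genome_crossref(sc$prs[1, ], sc$genomes)
  expect_equal(nrow(m), 1)
  expect_gte(m$identity, 0.95)
  expect_lte(m$evalue, 1e-5)
  # recovered interval overlaps the planted one tightly
  jac <- (min(m$end, sc$copy_end) - max(m$beg, sc$copy_beg)) /
    (max(m$end, sc$copy_end) - min(m$beg, sc$copy_beg))
  expect_gte(jac, 0.9)

  far <- make_scene(72, copy_mut = 0.08) # ~92% identity: below the cutoff
  expect_equal(nrow(genome_crossref(far$prs[1, ], far$genomes)), 0)
})

test_that("stop-codon scanning counts planted stops and flags frameshifts", {
  clean <- make_scene(73)
  m <- genome_crossref(clean$prs[1, ], clean$genomes)
  sc0 <- stop_codon_scan(m[1, ], clean$prs[1, ], clean$genomes, clean$panel)
  expect_equal(sc0$internal_stop_count, 0)
  expect_false(sc0$frameshift_suspected)

  two <- make_scene(74, stops = 2)
  m2 <- genome_crossref(two$prs[1, ], two$genomes)
  sc2 <- stop_codon_scan(m2[1, ], two$prs[1, ], two$genomes, two$panel)
  expect_equal(sc2$internal_stop_count, 2)

  fs <- make_scene(75, frameshift = TRUE)
  m3 <- genome_crossref(fs$prs[1, ], fs$genomes)
  expect_gte(nrow(m3), 1)
  sc3 <- stop_codon_scan(m3[1, ], fs$prs[1, ], fs$genomes, fs$panel)
  expect_true(sc3$frameshift_suspected)
})

test_that("TE flank scanning respects the 500-nt window and contig edges", {
  withr::local_seed(76)
  te_lib <- seq_set("te1", rand_nt(400), moltype = "NT")
  near <- make_scene(77, te_dist = 100, te_library = te_lib)
  m <- genome_crossref(near$prs[1, ], near$genomes)
  fl <- te_flank_scan(m[1, ], near$genomes, te_lib)
  expect_true(fl$te_flank_5)
  expect_false(fl$te_flank_3)
  expect_false(fl$at_scaffold_edge)

  far <- make_scene(78, te_dist = 600, te_library = te_lib)
  m <- genome_crossref(far$prs[1, ], far$genomes)
  fl <- te_flank_scan(m[1, ], far$genomes, te_lib)
  expect_false(fl$te_flank_5)

  edge <- make_scene(79, lead = 120) # match close to the contig start
  m <- genome_crossref(edge$prs[1, ], edge$genomes)
  fl <- te_flank_scan(m[1, ], edge$genomes, te_lib)
  expect_true(fl$at_scaffold_edge)
  expect_false(fl$te_flank_5)

  unscanned <- te_flank_scan(m[1, ], edge$genomes,
                             seq_set(character(), character(),
                                     moltype = "NT"))
  expect_true(is.na(unscanned$te_flank_5))
})

test_that("TE flags survive reverse-complementing the contig", {
  withr::local_seed(80)
  te_lib <- seq_set("te1", rand_nt(400), moltype = "NT")
  sc <- make_scene(81, te_dist = 100, te_library = te_lib)
  m <- genome_crossref(sc$prs[1, ], sc$genomes)
  fl <- te_flank_scan(m[1, ], sc$genomes, te_lib)
  rc <- sc
  rc$genomes[[1]]$targets$seq <- oracle_revcomp(sc$genomes[[1]]$targets$seq)
  m_rc <- genome_crossref(rc$prs[1, ], rc$genomes)
  fl_rc <- te_flank_scan(m_rc[1, ], rc$genomes, te_lib)
  # the 5' flank of the forward match is the 3' flank after revcomp
  expect_equal(fl$te_flank_5, fl_rc$te_flank_3)
  expect_equal(fl$te_flank_3, fl_rc$te_flank_5)
})

test_that("intact NS+VP assessment needs complete stop-free ORFs", {
  withr::local_seed(82)
  panel <- tiny_panel()
  ns_cds <- rand_cds(parvoscreen:::mutate_protein(
    panel$proteins$seq[1], 0.1, keep_start = TRUE), add_stop = TRUE)
  vp_cds <- rand_cds(parvoscreen:::mutate_protein(
    panel$proteins$seq[2], 0.1, keep_start = TRUE), add_stop = TRUE)
  cassette <- paste0(ns_cds, rand_nt(150), vp_cds)
  contig <- paste0(rand_nt(2000), cassette, rand_nt(2000))
  genomes <- list(list(dataset_id = "gnA", host_lineage = "x;y",
                       targets = seq_set("ctg1", contig, moltype = "NT")))
  prs <- data.frame(prs_id = "PRS0001", dataset_id = "txA", target_id = "t",
                    t_beg = 0L, t_end = nchar(cassette), strand = "+",
                    gene_class = "NS_VP",
                    recip_ref_id = panel$proteins$id[1],
                    seq = cassette, stringsAsFactors = FALSE)
  m <- genome_crossref(prs[1, ], genomes)
  expect_true(assess_intact_ns_vp(prs[1, ], m, genomes, panel))

  # one stop inserted into the VP ORF breaks intactness
  broken <- contig
  stop_at <- 2000 + nchar(ns_cds) + 150 + 3 * 150 # codon 151 of VP
  substr(broken, stop_at + 1, stop_at + 3) <- "TAA"
  genomes2 <- list(list(dataset_id = "gnA", host_lineage = "x;y",
                        targets = seq_set("ctg1", broken, moltype = "NT")))
  m2 <- genome_crossref(prs[1, ], genomes2)
  expect_false(assess_intact_ns_vp(prs[1, ], m2, genomes2, panel))

  # no genomic match: false by definition
  expect_false(assess_intact_ns_vp(prs[1, ],
                                   parvoscreen:::genomic_match_empty(),
                                   genomes, panel))
})
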