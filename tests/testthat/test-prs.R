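# Stage-1 tests share one small planted dataset built in code.
make_tx_dataset <- function(panel, seed = 61) {
  withr::with_seed(seed, {
    ns <- panel$proteins$seq[1]
    vp <- panel$proteins$seq[2]
    ns_div <- parvoscreen:::mutate_protein(ns, 0.4) # 60%-identity NS relic
    t1 <- paste0(rand_nt(120), rand_cds(ns_div), rand_nt(90))
    # bicistronic target: NS locus then VP locus within 6 kb
    t2 <- paste0(rand_nt(150), rand_cds(parvoscreen:::mutate_protein(ns, 0.2)),
                 rand_nt(400), rand_cds(parvoscreen:::mutate_protein(vp, 0.2)),
                 rand_nt(100))
    t3 <- rand_nt(1200) # background only
    seq_set(c("t1", "t2", "t3"), c(t1, t2, t3), moltype = "NT")
  })
}

tx_descriptor <- function() {
  list(dataset_id = "dsA", kind = "TRANSCRIPTOME",
       host_lineage = "Metazoa;Arthropoda;Insecta", path = NA)
}

test_that("forward search finds diverged relics under the E-value cutoff", {
  panel <- tiny_panel()
  targets <- make_tx_dataset(panel)
  hits <- forward_search(panel, tx_descriptor(), targets = targets)
  expect_true(any(hits$target_id == "t1" & hits$evalue < 1e-3))
  expect_false(any(hits$target_id == "t3")) # pure background stays clean
})

test_that("the forward E-value boundary is inclusive at the cutoff", {
  panel <- tiny_panel()
  targets <- make_tx_dataset(panel)
  hits <- forward_search(panel, tx_descriptor(), targets = targets,
                         evalue_max = 1)
  e <- min(hits$evalue[hits$target_id == "t1"])
  at <- forward_search(panel, tx_descriptor(), targets = targets,
                       evalue_max = e)
  expect_true(any(at$target_id == "t1")) # exactly at the cutoff: kept
  below <- forward_search(panel, tx_descriptor(), targets = targets,
                          evalue_max = e * 0.99)
  expect_false(any(below$target_id == "t1")) # just above the cutoff: dropped
})

test_that("reciprocal confirmation separates panel relics from decoy kin", {
  withr::local_seed(62)
  panel <- tiny_panel()
  # decoy family: far from the panel, close to the planted impostor
  decoy <- parvoscreen:::mutate_protein(panel$proteins$seq[1], 0.55)
  decoys <- seq_set(c("decoyA", "decoyB"),
                    c(decoy, rand_protein(300)), moltype = "AA")
  impostor <- parvoscreen:::mutate_protein(decoy, 0.05)
  targets <- make_tx_dataset(panel)
  targets <- rbind(targets,
                   data.frame(id = "t4", desc = "",
                              seq = paste0(rand_nt(100), rand_cds(impostor),
                                           rand_nt(100)),
                              stringsAsFactors = FALSE))
  ds <- tx_descriptor()
  hits <- forward_search(panel, ds, targets = targets)
  prs <- reciprocal_confirm(hits, panel, decoys, targets, ds)
  expect_true("t1" %in% prs$target_id) # genuine relic confirmed
  expect_equal(prs$gene_class[prs$target_id == "t1"], "NS")
  expect_false("t4" %in% prs$target_id) # best reciprocal hit is the decoy
  # confirmation never adds loci beyond the candidates
  expect_true(all(prs$target_id %in% hits$target_id))
})

test_that("NS and VP loci on one target merge into an NS_VP record", {
  panel <- tiny_panel()
  decoys <- tiny_decoys()
  targets <- make_tx_dataset(panel)
  ds <- tx_descriptor()
  hits <- forward_search(panel, ds, targets = targets)
  prs <- reciprocal_confirm(hits, panel, decoys, targets, ds)
  expect_equal(prs$gene_class[prs$target_id == "t2"], "NS_VP")
  expect_error(
    reciprocal_confirm(transform(hits, target_id = "nope"), panel, decoys,
                       targets, ds), "unknown target")
})

test_that("gene-class counts are stable under record order permutation", {
  withr::local_seed(63)
  panel <- tiny_panel()
  decoys <- tiny_decoys()
  targets <- make_tx_dataset(panel)
  ds <- tx_descriptor()
  counts <- function(tt) {
    h <- forward_search(panel, ds, targets = tt)
    p <- reciprocal_confirm(h, panel, decoys, tt, ds)
    table(p$gene_class)
  }
  perm <- targets[c(3, 1, 2), , drop = FALSE]
  attr(perm, "moltype") <- "NT"
  expect_equal(counts(targets), counts(perm))
})
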