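make_refs <- function(seed = 91, n = 4, len = 191) {
  withr::with_seed(seed, {
    root <- rand_protein(len)
    seq_set(paste0("ref", 1:n),
            c(root, vapply(2:n, function(i)
              parvoscreen:::mutate_protein(root, 0.25), "")),
            moltype = "AA")
  })
}

test_that("SF3 extraction finds planted domains and rejects noise", {
  withr::local_seed(92)
  refs <- make_refs()
  # a panel-like protein carrying its own reference fragment
  self <- paste0(rand_protein(120), refs$seq[1], rand_protein(150))
  hit <- extract_sf3(self, refs)
  expect_false(is.null(hit))
  expect_equal(hit$best_ref, "ref1")
  expect_lte(nchar(hit$fragment), 191)
  # planted diverged motif at a known offset
  motif <- parvoscreen:::mutate_protein(refs$seq[1], 0.3)
  prot <- paste0(rand_protein(120), motif, rand_protein(100))
  hit2 <- extract_sf3(prot, refs)
  expect_false(is.null(hit2))
  expect_lt(hit2$frag_beg, 120 + nchar(motif))
  expect_gt(hit2$frag_end, 120)
  # unrelated random protein: no call
  expect_null(extract_sf3(rand_protein(500), refs))
})

test_that("identical sequences align without gaps", {
  withr::local_seed(93)
  s <- rand_protein(100)
  msa <- progressive_msa(seq_set(paste0("s", 1:5), rep(s, 5),
                                 moltype = "AA"))
  expect_true(all(msa$aln == s))
  expect_error(progressive_msa(seq_set("a", s, moltype = "AA")),
               "at least 2")
})

test_that("two-sequence alignment matches the pairwise DP oracle", {
  withr::local_seed(94)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (i in 1:10) {
    a <- rand_protein(80)
    b <- parvoscreen:::mutate_protein(a, 0.2)
    msa <- progressive_msa(seq_set(c("a", "b"), c(a, b), moltype = "AA"))
    # end-gap-free global score of the produced alignment vs the oracle
    want <- as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
      substitutionMatrix = env$BLOSUM62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE))
    got <- parvoscreen:::cpp_nw_profile(
      outer(strsplit(a, "")[[1]], strsplit(b, "")[[1]],
            Vectorize(function(x, y) env$BLOSUM62[x, y])),
      11, 1, TRUE)$score
    expect_equal(got, want)
  }
})

test_that("ungapping alignment rows reproduces the inputs exactly", {
  withr::local_seed(95)
  root <- rand_protein(150)
  frs <- vapply(1:8, function(i) {
    s <- parvoscreen:::mutate_protein(root, 0.2)
    if (runif(1) < 0.5) # indel: drop a short internal block
      s <- paste0(substr(s, 1, 60), substr(s, 66, nchar(s)))
    s
  }, "")
  x <- seq_set(paste0("f", 1:8), frs, moltype = "AA")
  msa <- progressive_msa(x)
  expect_equal(length(unique(nchar(msa$aln))), 1)
  expect_identical(unname(vapply(msa$aln, parvoscreen:::ungap, "")), x$seq)
  expect_error(progressive_msa(seq_set(c("f1", "f1x"), frs[1:2],
                                       moltype = "AA")[c(1, 1), ]),
               "duplicate")
})

test_that("low-divergence families align nearly column-perfect", {
  # substitution-only family: the true alignment is positional, so a good
  # progressive alignment should recover (nearly) all homologous columns
  withr::local_seed(96)
  root <- rand_protein(200)
  fam <- vapply(1:10, function(i) parvoscreen:::mutate_protein(root, 0.1), "")
  msa <- progressive_msa(seq_set(paste0("s", 1:10), fam, moltype = "AA"))
  gapfree <- mean(!grepl("-", do.call(
    paste0, strsplit(unname(msa$aln), ""))))
  expect_gte(gapfree, 0.9)
})

test_that("p-distances count mismatches over comparable columns", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  expect_equal(p_distance_matrix(aln)["a", "b"], 0)
  withr::local_seed(97)
  base <- strsplit(rand_protein(100), "")[[1]]
  other <- base
  other[c(10, 50, 90)] <- vapply(base[c(10, 50, 90)], function(x)
    setdiff(AA20, x)[1], "")
  aln2 <- c(a = paste(base, collapse = ""),
            b = paste(other, collapse = ""))
  expect_equal(p_distance_matrix(aln2)["a", "b"], 0.03)
  # independent recount oracle on gapped random alignments
  msa <- progressive_msa(seq_set(paste0("s", 1:6), vapply(1:6, function(i)
    parvoscreen:::mutate_protein(paste(base, collapse = ""), 0.3), ""),
    moltype = "AA"))
  d <- p_distance_matrix(msa)
  M <- strsplit(unname(msa$aln), "")
  for (i in 1:5) for (j in (i + 1):6) {
    comp <- M[[i]] != "-" & M[[j]] != "-"
    expect_equal(d[i, j], sum(M[[i]][comp] != M[[j]][comp]) / sum(comp))
    expect_equal(d[i, j], d[j, i])
  }
  # a pair with no shared columns errors under pairwise deletion
  expect_error(p_distance_matrix(c(x = "AA--", y = "--CC")),
               "no comparable columns")
})

test_that("neighbor joining satisfies 3-taxon closed forms and symmetry", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  withr::local_seed(98)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    got <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), got), 0)
    # taxon order permutation leaves the unrooted topology unchanged
    p <- sample(n)
    got2 <- nj_tree(d[p, p])
    expect_equal(phangorn::RF.dist(got, got2), 0)
  }
})

test_that("bootstrap supports are seeded, reproducible and strong on clean signal", {
  withr::local_seed(99)
  msa <- simulate_alignment()
  t1 <- bootstrap_support(msa, replicates = 100, seed = 7)
  t2 <- bootstrap_support(msa, replicates = 100, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  sup <- attr(t1, "support")
  # every true bipartition (a-side vs b-side splits) should be near-certain
  expect_gte(min(sup[-1]), 0.95)
})

test_that("outgroup rooting preserves ingroup structure", {
  withr::local_seed(100)
  msa <- simulate_alignment()
  og <- parvoscreen:::mutate_protein(msa$aln[["a1"]], 0.5)
  msa$aln <- c(msa$aln, outg = og)
  msa$ids <- c(msa$ids, "outg")
  tr <- bootstrap_support(msa, replicates = 50, seed = 3)
  rooted <- root_with_outgroup(tr, "outg")
  expect_true(ape::is.rooted(rooted))
  # the outgroup is sister to everything else
  og_tip <- which(rooted$tip.label == "outg")
  root_node <- length(rooted$tip.label) + 1
  expect_true(any(rooted$edge[, 1] == root_node &
                    rooted$edge[, 2] == og_tip))
  # rooting then unrooting returns the original bipartition set
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(rooted), ape::unroot(tr)), 0)
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")
})

test_that("clade annotation applies the strict support threshold", {
  tr <- ape::read.tree(text = "(((p1:1,p2:1)x:1,(p3:1,p4:1)y:1)z:1,o:3);")
  tr$node.label <- c("", "0.90", "0.90", "0.70") # root, z, x, y
  phylum <- c(p1 = "Arthropoda", p2 = "Arthropoda", p3 = "Mollusca",
              p4 = "Mollusca", o = "Chordata")
  is_prs <- c(p1 = TRUE, p2 = FALSE, p3 = TRUE, p4 = TRUE, o = FALSE)
  rep <- annotate_clades(tr, phylum, is_prs, support_min = 0.70)
  # clade y sits exactly at 0.70: excluded under the strict rule
  expect_equal(rep$phylum, "Arthropoda")
  expect_equal(rep$n_prs, 1)
  none <- annotate_clades(tr, phylum, is_prs, support_min = 0.95)
  expect_equal(nrow(none), 0)
})
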