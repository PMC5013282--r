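# Shared fixture builders and independent oracles. Everything is generated
# in code under explicit seeds; no stored data files.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
NT4 <- c("A", "C", "G", "T")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

# independent codon-by-codon translation oracle (plain lookup, no shared
# code path with the package's vectorised translator)
ORACLE_CODE <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aa, codons)
})

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (cod %in% names(ORACLE_CODE)) ORACLE_CODE[[cod]] else "X"
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# independent exhaustive ORF oracle implementing the documented per-stretch
# rule directly on codon strings
oracle_orfs <- function(nt, orf_min_nt = 300) {
  out <- list()
  L <- nchar(nt)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else oracle_revcomp(nt)
    for (phase in 0:2) {
      nc <- (L - phase) %/% 3
      if (nc < 1) next
      cods <- substring(s, phase + 1 + 3 * (0:(nc - 1)),
                        phase + 3 * (1:nc))
      aa <- vapply(cods, function(cd)
        if (cd %in% names(ORACLE_CODE)) ORACLE_CODE[[cd]] else "X", "")
      stops <- which(aa == "*")
      seg_beg <- c(1, stops + 1)
      seg_stop <- c(stops, NA)
      for (k in seq_along(seg_beg)) {
        b <- seg_beg[k]; stp <- seg_stop[k]
        e <- if (is.na(stp)) nc else stp
        if (b > e) next
        anchored5 <- b > 1
        anchored3 <- !is.na(stp)
        if (anchored5) {
          cand_last <- e - as.integer(anchored3)
          if (cand_last < b) next
          mm <- which(aa[b:cand_last] == "M")
          if (!length(mm)) next
          start <- b + mm[1] - 1
        } else start <- b
        len <- (e - start + 1) * 3
        if (len <= orf_min_nt) next
        if (strand == "+") {
          beg_nt <- phase + 3 * (start - 1)
          end_nt <- phase + 3 * e
        } else {
          beg_nt <- L - phase - 3 * e
          end_nt <- L - phase - 3 * (start - 1)
        }
        comp <- if (anchored5 && anchored3) "COMPLETE"
        else if (anchored3) "TRUNCATED_5"
        else if (anchored5) "TRUNCATED_3"
        else "TRUNCATED_BOTH"
        out[[length(out) + 1]] <- data.frame(
          beg = beg_nt, end = end_nt, strand = strand,
          completeness = comp, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(beg = integer(), end = integer(),
                                      strand = character(),
                                      completeness = character()))
  res <- do.call(rbind, out)
  res[order(res$beg, res$end, res$strand), , drop = FALSE]
}

# reverse-translate a protein with uniform codon choice (test-local)
rand_cds <- function(aa, add_stop = FALSE) {
  tab <- split(names(ORACLE_CODE), unname(ORACLE_CODE))
  cods <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, "")
  paste0(paste(cods, collapse = ""), if (add_stop) "TAA" else "")
}

# Biostrings full-DP oracle score for protein local alignment
oracle_sw_score <- function(a, b) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = env$BLOSUM62, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE))
}

# small 2-genus panel for unit tests
tiny_panel <- function(seed = 42) {
  withr::with_seed(seed, {
    ns1 <- paste0("M", rand_protein(299))
    vp1 <- paste0("M", rand_protein(329))
    panel_prot <- seq_set(
      c("gA_sp1_NS", "gA_sp1_VP", "gB_sp1_NS", "gB_sp1_VP", "outg"),
      c(ns1, vp1,
        parvoscreen:::mutate_protein(ns1, 0.35, keep_start = TRUE),
        parvoscreen:::mutate_protein(vp1, 0.35, keep_start = TRUE),
        parvoscreen:::mutate_protein(ns1, 0.55, keep_start = TRUE)),
      moltype = "AA")
    ann <- data.frame(
      id = panel_prot$id,
      gene = c("NS", "VP", "NS", "VP", "OTHER"),
      genus = c("gA", "gA", "gB", "gB", ""),
      host_lineage = c(rep("Metazoa;Arthropoda;Insecta", 2),
                       rep("Metazoa;Chordata;Mammalia", 2), ""),
      is_outgroup = c(FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
    parvoscreen:::make_reference_panel(panel_prot, ann)
  })
}

tiny_decoys <- function(seed = 43) {
  withr::with_seed(seed, {
    seq_set(c("dec1", "dec2"), c(rand_protein(300), rand_protein(300)),
            moltype = "AA")
  })
}

# scaled-down benchmark for pipeline-level tests
small_benchmark <- function(seed = 5) {
  cfg <- generator_config(
    seed = seed, transcripts_per_host = 12L, transcript_len = c(300L, 800L),
    contig_len = 10000L, n_extant = 3L, n_intact = 1L, n_degraded = 2L,
    n_contaminant = 1L, n_decoy = 1L)
  pan <- generate_panel(cfg)
  generate_host_datasets(cfg, pan)
}

run_small_pipeline <- function(bench, dir, seed = 5, ...) {
  bdir <- file.path(dir, "bench")
  paths <- write_benchmark(bench, bdir)
  cfg <- pipeline_config(
    panel_fasta = paths$panel, panel_annotations = paths$panel_annotations,
    manifest = paths$manifest, decoys_fasta = paths$decoys,
    te_library_fasta = paths$te_library, sf3_refs_fasta = paths$sf3_refs,
    out_dir = file.path(dir, "run"), seed = seed, bootstrap = 50L, ...)
  run_pipeline(cfg)
}

# substitution-only alignment simulated down a fixed balanced 8-tip tree;
# every internal edge carries signal
simulate_alignment <- function(ncol = 400, rate = 0.08) {
  tips <- list()
  root <- rand_protein(ncol)
  for (cl in c("a", "b")) {
    anc <- parvoscreen:::mutate_protein(root, rate)
    x1 <- parvoscreen:::mutate_protein(anc, rate)
    x2 <- parvoscreen:::mutate_protein(anc, rate)
    tips[[paste0(cl, 1)]] <- parvoscreen:::mutate_protein(x1, rate)
    tips[[paste0(cl, 2)]] <- parvoscreen:::mutate_protein(x1, rate)
    tips[[paste0(cl, 3)]] <- parvoscreen:::mutate_protein(x2, rate)
    tips[[paste0(cl, 4)]] <- parvoscreen:::mutate_protein(x2, rate)
  }
  structure(list(ids = names(tips), aln = unlist(tips)), class = "msa")
}
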