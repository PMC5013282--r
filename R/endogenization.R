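# Stage 2: genomic cross-referencing and degradation evidence.

#' Cross-reference a PRS against genome datasets
#'
#' Nucleotide-mode search of the PRS sequence against each genome; only
#' matches passing BOTH cutoffs (identity over aligned columns and E-value)
#' are stored.
#'
#' @param prs one row of a PRS table ([reciprocal_confirm()]).
#' @param genomes list of loaded genome datasets: each element a list with
#'   `dataset_id` and `targets` (an NT [seq_set()]); see
#'   [load_genome_datasets()].
#' @param identity_min minimum nucleotide identity (default 0.95).
#' @param evalue_max E-value cutoff (default `1e-5`).
#' @param scheme a [scoring_scheme_nt()].
#' @return data frame of genomic matches (`prs_id`, `genome_dataset_id`,
#'   `contig_id`, `beg`, `end`, `identity`, `evalue`, `score`, `strand`).
#' @export
genome_crossref <- function(prs, genomes, identity_min = 0.95,
                            evalue_max = 1e-5, scheme = scoring_scheme_nt()) {
  q <- seq_set(prs$prs_id, prs$seq, moltype = "NT")
  out <- list()
  for (g in genomes) {
    hits <- search_nucleotide(q, g$targets, scheme, evalue_max = evalue_max)
    hits <- hits[hits$identity >= identity_min, , drop = FALSE]
    if (!nrow(hits)) next
    out[[length(out) + 1]] <- data.frame(
      prs_id = prs$prs_id, genome_dataset_id = g$dataset_id,
      contig_id = hits$target_id, beg = hits$t_beg, end = hits$t_end,
      identity = hits$identity, evalue = hits$evalue, score = hits$score,
      strand = ifelse(hits$frame == "NT-", "-", "+"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(genomic_match_empty())
  res <- do.call(rbind, out)
  res <- res[stable_order(res$evalue, -res$score, res$genome_dataset_id,
                          res$contig_id, res$beg), , drop = FALSE]
  rownames(res) <- NULL
  res
}

genomic_match_empty <- function() {
  data.frame(prs_id = character(), genome_dataset_id = character(),
             contig_id = character(), beg = integer(), end = integer(),
             identity = numeric(), evalue = numeric(), score = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Load genome datasets from a manifest
#'
#' @param manifest data frame from [read_dataset_manifest()].
#' @return list of `list(dataset_id, host_lineage, targets)` for every
#'   GENOME row.
#' @export
load_genome_datasets <- function(manifest) {
  g <- manifest[manifest$kind == "GENOME", , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i)
    list(dataset_id = g$dataset_id[i], host_lineage = g$host_lineage[i],
         targets = read_fasta(g$path[i], "NT")))
}

get_contig <- function(genomes, dataset_id, contig_id) {
  for (g in genomes) {
    if (g$dataset_id == dataset_id) {
      i <- match(contig_id, g$targets$id)
      if (is.na(i)) stop("unknown contig: ", contig_id)
      return(g$targets$seq[i])
    }
  }
  stop("unknown genome dataset: ", dataset_id)
}

#' Scan a genomic match for internal stop codons and frameshifts
#'
#' The genomic locus is re-aligned with the PRS's best reference protein;
#' the reading frame of the best hit defines where stops are counted. A
#' stop aligned at the last codon of the alignment is the biological stop
#' and not counted as internal. A frameshift is suspected when a chained
#' two-frame alignment beats the best single-frame alignment by more than
#' `frameshift_margin` raw score units.
#'
#' @param match one genomic match row ([genome_crossref()]).
#' @param prs the matching PRS row.
#' @param genomes loaded genome datasets ([load_genome_datasets()]).
#' @param panel reference panel (source of the reference protein).
#' @param scheme protein [scoring_scheme()].
#' @param frameshift_margin raw score margin (default 15).
#' @param flank_nt context added on each side of the locus before
#'   re-alignment (default 99, a multiple of 3).
#' @return list with `internal_stop_count` (NA when the locus is shorter
#'   than 60 nt: evidence unavailable, not zero) and `frameshift_suspected`.
#' @export
stop_codon_scan <- function(match, prs, genomes, panel,
                            scheme = scoring_scheme(), frameshift_margin = 15,
                            flank_nt = 99) {
  contig <- get_contig(genomes, match$genome_dataset_id, match$contig_id)
  if (match$end - match$beg < 60) {
    return(list(internal_stop_count = NA_integer_,
                frameshift_suspected = NA))
  }
  beg <- max(0, match$beg - flank_nt)
  end <- min(nchar(contig), match$end + flank_nt)
  locus <- substr(contig, beg + 1, end)
  ref_id <- prs$recip_ref_id
  ref <- panel$proteins[panel$proteins$id == ref_id, , drop = FALSE]
  hits <- search_translated(ref, seq_set("locus", locus, moltype = "NT"),
                            scheme, evalue_max = Inf)
  if (!nrow(hits)) {
    return(list(internal_stop_count = NA_integer_,
                frameshift_suspected = NA))
  }
  best <- hits[1, ]
  frames <- translate_six_frames(locus)
  labels <- vapply(frames, `[[`, "", "frame")
  # internal stops: '*' strictly inside the aligned codons of the best frame
  fr <- frames[[match(best$frame, labels)]]
  iv <- aligned_codon_range(fr, best)
  pep <- substr(fr$peptide, iv[1] + 1, iv[2])
  stops <- gregexpr("*", pep, fixed = TRUE)[[1]]
  n_stop <- if (stops[1] == -1) 0L else {
    # a stop at the final aligned codon is the biological terminator
    sum(stops < nchar(pep))
  }
  # frameshift: best colinear chain of two hits in different frames
  fs <- FALSE
  if (nrow(hits) > 1) {
    for (i in seq_len(nrow(hits) - 1)) {
      for (j in (i + 1):nrow(hits)) {
        hi <- hits[i, ]; hj <- hits[j, ]
        if (hi$frame == hj$frame) next
        if (frame_sign(hi$frame) != frame_sign(hj$frame)) next
        q_olap <- min(hi$q_end, hj$q_end) - max(hi$q_beg, hj$q_beg)
        t_olap <- min(hi$t_end, hj$t_end) - max(hi$t_beg, hj$t_beg)
        min_q <- min(hi$q_end - hi$q_beg, hj$q_end - hj$q_beg)
        if (t_olap > 0.3 * min_q * 3 || q_olap > 0.3 * min_q) next
        colinear <- (hi$q_beg < hj$q_beg) == (hi$t_beg < hj$t_beg)
        if (frame_sign(hi$frame) == "-")
          colinear <- (hi$q_beg < hj$q_beg) == (hi$t_beg > hj$t_beg)
        if (!colinear) next
        if (hi$score + hj$score > best$score + frameshift_margin) fs <- TRUE
      }
    }
  }
  list(internal_stop_count = n_stop, frameshift_suspected = fs)
}

# Map a hit's forward-strand nt interval back to the frame's codon range
# (0-based half-open codon indices on the frame peptide).
aligned_codon_range <- function(fr, hit) {
  L <- fr$nt_len
  if (fr$strand == "+") {
    b <- (hit$t_beg - fr$phase) %/% 3
    e <- (hit$t_end - fr$phase) %/% 3
  } else {
    b <- (L - fr$phase - hit$t_end) %/% 3
    e <- (L - fr$phase - hit$t_beg) %/% 3
  }
  c(max(0L, b), min(nchar(fr$peptide), e))
}

#' Scan the flanks of a genomic match for transposable elements
#'
#' Up to `window_nt` nucleotides on each side of the match are extracted
#' (clipped at contig ends, setting the scaffold-edge flag) and searched
#' against the TE library in nucleotide mode. A side is flagged iff a hit
#' covers at least `min_cover_nt` of the flank at `min_identity` or better.
#' An empty TE library leaves the flags NA ("unscanned").
#'
#' @param match one genomic match row.
#' @param genomes loaded genome datasets.
#' @param te_library NT [seq_set()] of TE / repeat consensus sequences.
#' @param window_nt flank window (default 500).
#' @param min_cover_nt,min_identity flag thresholds (defaults 80 nt, 0.80).
#' @param scheme a [scoring_scheme_nt()].
#' @return list with `te_flank_5`, `te_flank_3` (logical or NA) and
#'   `at_scaffold_edge`.
#' @export
te_flank_scan <- function(match, genomes, te_library, window_nt = 500,
                          min_cover_nt = 80, min_identity = 0.80,
                          scheme = scoring_scheme_nt()) {
  contig <- get_contig(genomes, match$genome_dataset_id, match$contig_id)
  L <- nchar(contig)
  f5_beg <- max(0, match$beg - window_nt)
  f5 <- substr(contig, f5_beg + 1, match$beg)
  f3 <- substr(contig, match$end + 1, min(L, match$end + window_nt))
  at_edge <- (match$beg - f5_beg < window_nt) ||
    (min(L, match$end + window_nt) - match$end < window_nt)
  if (!nrow(te_library)) {
    return(list(te_flank_5 = NA, te_flank_3 = NA, at_scaffold_edge = at_edge))
  }
  flag_side <- function(flank) {
    if (nchar(flank) < scheme$word) return(FALSE)
    hits <- search_nucleotide(te_library, seq_set("flank", flank, moltype = "NT"),
                              scheme, evalue_max = Inf)
    any(hits$t_end - hits$t_beg >= min_cover_nt &
          hits$identity >= min_identity)
  }
  list(te_flank_5 = flag_side(f5), te_flank_3 = flag_side(f3),
       at_scaffold_edge = at_edge)
}

#' Assess whether a genomic locus carries intact NS and VP ORFs
#'
#' TRUE iff the genomic region around the PRS's matches contains COMPLETE
#' ORFs (> `orf_min_nt`) covering at least `min_cover` of both an NS-class
#' and a VP-class aligned region. COMPLETE ORFs are stop-free by
#' construction, so the zero-internal-stop requirement is implied.
#'
#' @param prs one PRS row.
#' @param matches genomic matches of this PRS.
#' @param genomes loaded genome datasets.
#' @param panel reference panel.
#' @param scheme protein [scoring_scheme()].
#' @param orf_min_nt strict ORF length cutoff (default 300).
#' @param min_cover required coverage of each gene's aligned region
#'   (default 0.8).
#' @param region_pad_nt context around the matched interval searched for the
#'   two ORFs (default 4000, enough to span a parvovirus-sized locus).
#' @return logical flag.
#' @export
assess_intact_ns_vp <- function(prs, matches, genomes, panel,
                                scheme = scoring_scheme(), orf_min_nt = 300,
                                min_cover = 0.8, region_pad_nt = 4000) {
  if (!nrow(matches)) return(FALSE)
  best <- matches[which.max(matches$end - matches$beg), ]
  contig <- get_contig(genomes, best$genome_dataset_id, best$contig_id)
  beg <- max(0, best$beg - region_pad_nt)
  end <- min(nchar(contig), best$end + region_pad_nt)
  region <- substr(contig, beg + 1, end)
  region_set <- seq_set("region", region, moltype = "NT")
  orfs <- find_orfs(region, orf_min_nt = orf_min_nt)
  orfs <- orfs[orfs$completeness == "COMPLETE", , drop = FALSE]
  if (!nrow(orfs)) return(FALSE)
  covered <- function(gene) {
    qs <- panel$proteins[panel$annotations$gene == gene &
                           !panel$annotations$is_outgroup, , drop = FALSE]
    hits <- search_translated(qs, region_set, scheme, evalue_max = 1e-3)
    if (!nrow(hits)) return(FALSE)
    h <- hits[1, ] # best-supported aligned region for this gene class
    len <- h$t_end - h$t_beg
    # a single complete ORF must span the aligned region: two part-ORFs
    # separated by a premature stop do not count as intact
    ov <- pmax(0, pmin(orfs$end, h$t_end) - pmax(orfs$beg, h$t_beg))
    ov[frame_sign(orfs$frame) != frame_sign(h$frame)] <- 0
    max(ov) >= min_cover * len
  }
  covered("NS") && covered("VP")
}

#' Gather the full evidence bundle for every PRS
#'
#' Runs [genome_crossref()], then — when at least one genomic match exists —
#' [stop_codon_scan()], [te_flank_scan()] and [assess_intact_ns_vp()] on the
#' best match.
#'
#' @param prs_table PRS table.
#' @param genomes loaded genome datasets.
#' @param te_library NT [seq_set()] (may be empty: TE flags stay NA).
#' @param panel reference panel.
#' @param config a [pipeline_config()].
#' @return list with `evidence` (one row per PRS) and `matches` (all stored
#'   genomic matches).
#' @export
gather_evidence <- function(prs_table, genomes, te_library, panel,
                            config = pipeline_config()) {
  ev <- list()
  gm <- list()
  for (i in seq_len(nrow(prs_table))) {
    prs <- prs_table[i, ]
    matches <- genome_crossref(prs, genomes,
                               identity_min = config$genomic_identity,
                               evalue_max = config$genomic_evalue)
    row <- data.frame(prs_id = prs$prs_id, n_genomic_matches = nrow(matches),
                      best_identity = NA_real_,
                      internal_stop_count = NA_integer_,
                      frameshift_suspected = NA, te_flank_5 = NA,
                      te_flank_3 = NA, intact_ns_vp = FALSE,
                      at_scaffold_edge = FALSE, stringsAsFactors = FALSE)
    if (nrow(matches)) {
      gm[[length(gm) + 1]] <- matches
      row$best_identity <- max(matches$identity)
      best <- matches[1, ]
      sc <- stop_codon_scan(best, prs, genomes, panel,
                            frameshift_margin = config$frameshift_margin)
      row$internal_stop_count <- sc$internal_stop_count
      row$frameshift_suspected <- sc$frameshift_suspected
      te <- te_flank_scan(best, genomes, te_library,
                          window_nt = config$flank_window)
      row$te_flank_5 <- te$te_flank_5
      row$te_flank_3 <- te$te_flank_3
      row$at_scaffold_edge <- te$at_scaffold_edge
      row$intact_ns_vp <- assess_intact_ns_vp(
        prs, matches, genomes, panel, orf_min_nt = config$orf_min_nt)
    }
    ev[[length(ev) + 1]] <- row
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(prs_id = character(), n_genomic_matches = integer(),
               best_identity = numeric(), internal_stop_count = integer(),
               frameshift_suspected = logical(), te_flank_5 = logical(),
               te_flank_3 = logical(), intact_ns_vp = logical(),
               at_scaffold_edge = logical(), stringsAsFactors = FALSE)
  matches <- if (length(gm)) do.call(rbind, gm) else genomic_match_empty()
  rownames(evidence) <- rownames(matches) <- NULL
  list(evidence = evidence, matches = matches)
}

#' Write genomic matches as a BED file
#'
#' 0-based half-open intervals, with name (prs_id), score (percent identity)
#' and strand columns.
#'
#' @param matches genomic match table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matches_bed <- function(matches, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.1f\t%s", matches$contig_id,
                   matches$beg, matches$end, matches$prs_id,
                   100 * matches$identity, matches$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
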