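# Stage 1: forward search, reciprocal confirmation, PRS records.

#' Forward search of a target dataset with the reference panel
#'
#' Panel proteins are searched against the dataset: translated mode for
#' transcriptome/genome datasets, protein-protein mode for protein datasets.
#' Only hits with `evalue <= evalue_max` are returned.
#'
#' @param panel a reference panel from [load_reference_panel()].
#' @param dataset one row of a dataset manifest ([read_dataset_manifest()]),
#'   or a list with `dataset_id`, `kind`, `path`.
#' @param evalue_max forward E-value cutoff (default `1e-3`).
#' @param scheme protein [scoring_scheme()].
#' @param targets optional pre-loaded [seq_set()] for the dataset (skips
#'   re-reading `dataset$path`).
#' @return hit table with a `dataset_id` column prepended.
#' @export
forward_search <- function(panel, dataset, evalue_max = 1e-3,
                           scheme = scoring_scheme(), targets = NULL) {
  kind <- dataset$kind
  if (evalue_max <= 0) { # degenerate cutoff: nothing can pass
    return(cbind(dataset_id = character(0), empty_hit_table()))
  }
  if (is.null(targets)) {
    targets <- read_fasta(dataset$path, if (kind == "PROTEIN") "AA" else "NT")
  }
  hits <- if (kind == "PROTEIN") {
    search_protein(panel$proteins, targets, scheme, evalue_max)
  } else {
    search_translated(panel$proteins, targets, scheme, evalue_max)
  }
  if (nrow(hits)) hits <- cbind(dataset_id = dataset$dataset_id, hits,
                                stringsAsFactors = FALSE)
  else hits <- cbind(dataset_id = character(0), hits)
  hits
}

frame_sign <- function(frame) {
  ifelse(substr(frame, 1, 1) == "-" | frame == "NT-", "-", "+")
}

# Merge candidate hit intervals on one target into loci: hits separated by
# less than `gap_nt` with the same frame sign join one locus.
merge_loci <- function(df, gap_nt = 300) {
  df$sign <- frame_sign(df$frame)
  out <- list()
  for (sg in unique(df$sign)) {
    d <- df[df$sign == sg, , drop = FALSE]
    d <- d[stable_order(d$t_beg, d$t_end), , drop = FALSE]
    beg <- d$t_beg[1]; end <- d$t_end[1]; idx <- list(rownames(d)[1])
    cur <- 1
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (d$t_beg[i] < end + gap_nt) {
          end <- max(end, d$t_end[i])
          idx[[cur]] <- c(idx[[cur]], rownames(d)[i])
        } else {
          out[[length(out) + 1]] <- list(beg = beg, end = end, sign = sg,
                                         rows = idx[[cur]])
          cur <- cur + 1
          beg <- d$t_beg[i]; end <- d$t_end[i]; idx[[cur]] <- rownames(d)[i]
        }
      }
    }
    out[[length(out) + 1]] <- list(beg = beg, end = end, sign = sg,
                                   rows = idx[[cur]])
  }
  out[order(vapply(out, `[[`, 0, "beg"), vapply(out, `[[`, 0, "end"))]
}

# Translated peptide of the best forward hit across a locus (used later for
# SF3 extraction); stops appear as '*'.
locus_peptide <- function(target_seq, hit) {
  if (hit$frame == "AA") return(substr(target_seq, hit$q_beg + 1, hit$q_end))
  sub <- substr(target_seq, hit$t_beg + 1, hit$t_end)
  if (frame_sign(hit$frame) == "-") sub <- reverse_complement(sub)
  translate_nt(sub)
}

#' Reciprocal confirmation of forward candidates
#'
#' Forward hits on one target are merged into loci (gap < 300 nt, same frame
#' sign). Each locus subsequence is searched back against the panel proteins
#' mixed with decoys; the locus is confirmed iff its best reciprocal hit
#' (lowest E-value, ties by score) is a panel protein with
#' `evalue <= evalue_max`. Confirmed NS and VP loci on one target within
#' `nsvp_span_nt` are merged into a single record with gene class `NS_VP`.
#'
#' @param candidates forward hit table (with `dataset_id`).
#' @param panel reference panel.
#' @param decoys AA [seq_set()] of non-parvoviral decoy proteins (stands in
#'   for the non-viral content of a real protein database; must be
#'   non-empty).
#' @param targets [seq_set()] holding every target referenced by
#'   `candidates`.
#' @param dataset the dataset descriptor row (for id, kind and lineage).
#' @param evalue_max reciprocal E-value cutoff (default `1e-3`).
#' @param scheme protein [scoring_scheme()].
#' @param locus_gap_nt locus merge gap (default 300).
#' @param nsvp_span_nt maximum NS-to-VP span for the `NS_VP` merge
#'   (default 6000, a typical parvovirus genome length).
#' @return a `prs` data frame: one row per confirmed locus with provenance,
#'   best forward/reciprocal statistics, locus sequence and peptide.
#' @export
reciprocal_confirm <- function(candidates, panel, decoys, targets, dataset,
                               evalue_max = 1e-3, scheme = scoring_scheme(),
                               locus_gap_nt = 300, nsvp_span_nt = 6000) {
  if (!nrow(decoys)) stop("decoy set must be non-empty")
  empty <- prs_empty()
  if (!nrow(candidates)) return(empty)
  unknown <- setdiff(candidates$target_id, targets$id)
  if (length(unknown)) stop("candidate references unknown target: ",
                            unknown[1])
  db <- seq_set(c(panel$proteins$id, decoys$id),
                c(panel$proteins$seq, decoys$seq), moltype = "AA")
  db_aa <- sum(nchar(db$seq))
  is_protein <- identical(dataset$kind, "PROTEIN")
  recs <- list()
  for (tid in unique(candidates$target_id)) {
    cand <- candidates[candidates$target_id == tid, , drop = FALSE]
    rownames(cand) <- as.character(seq_len(nrow(cand)))
    tseq <- targets$seq[targets$id == tid]
    loci <- merge_loci(cand, gap_nt = locus_gap_nt)
    for (lc in loci) {
      sub <- substr(tseq, lc$beg + 1, lc$end)
      if (!nzchar(sub)) next
      rhits <- reciprocal_hits(sub, db, db_aa, scheme, is_protein)
      if (!nrow(rhits)) next
      best <- rhits[1, ]
      if (!(best$protein_id %in% panel$proteins$id) ||
          best$evalue > evalue_max) next
      ann <- panel$annotations[panel$annotations$id == best$protein_id, ]
      lrows <- cand[lc$rows, , drop = FALSE]
      bf <- lrows[which.min(lrows$evalue), ]
      recs[[length(recs) + 1]] <- data.frame(
        dataset_id = dataset$dataset_id,
        host_lineage = dataset$host_lineage %||% "",
        target_id = tid, t_beg = lc$beg, t_end = lc$end,
        strand = lc$sign,
        gene_class = ann$gene,
        fwd_evalue = bf$evalue, fwd_score = bf$score,
        recip_evalue = best$evalue, recip_score = best$score,
        recip_ref_id = best$protein_id,
        ref_genus = ann$genus,
        best_reference_identity = max(lrows$identity),
        seq = sub, peptide = locus_peptide(tseq, bf),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty)
  prs <- do.call(rbind, recs)
  prs <- merge_ns_vp(prs, nsvp_span_nt, setNames(targets$seq, targets$id))
  prs <- prs[stable_order(prs$dataset_id, prs$target_id, prs$t_beg), ,
             drop = FALSE]
  prs$prs_id <- sprintf("PRS%04d", seq_len(nrow(prs)))
  rownames(prs) <- NULL
  prs[, c("prs_id", setdiff(names(prs), "prs_id"))]
}

prs_empty <- function() {
  data.frame(prs_id = character(), dataset_id = character(),
             host_lineage = character(), target_id = character(),
             t_beg = integer(), t_end = integer(), strand = character(),
             gene_class = character(), fwd_evalue = numeric(),
             fwd_score = integer(), recip_evalue = numeric(),
             recip_score = integer(), recip_ref_id = character(),
             ref_genus = character(), best_reference_identity = numeric(),
             seq = character(), peptide = character(),
             stringsAsFactors = FALSE)
}

# Best reciprocal hits of one locus against the panel+decoy protein set,
# ranked by (evalue asc, score desc). E-values treat the locus as the query
# (m = locus residues searched) and the protein set as the database.
reciprocal_hits <- function(locus_seq, db, db_aa, scheme, is_protein) {
  locus_set <- seq_set("locus", locus_seq,
                       moltype = if (is_protein) "AA" else "NT")
  hits <- if (is_protein) {
    search_protein(db, locus_set, scheme, evalue_max = Inf)
  } else {
    search_translated(db, locus_set, scheme, evalue_max = Inf)
  }
  if (!nrow(hits)) {
    return(data.frame(protein_id = character(), score = integer(),
                      evalue = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  m <- if (is_protein) nchar(locus_seq) else nchar(locus_seq) %/% 3
  out <- data.frame(protein_id = hits$query_id, score = hits$score,
                    evalue = evalue(hits$score, max(m, 1), db_aa, scheme),
                    identity = hits$identity, stringsAsFactors = FALSE)
  out[stable_order(out$evalue, -out$score, out$protein_id), , drop = FALSE]
}

# Merge confirmed NS and VP loci on one target into NS_VP records when their
# span fits a typical parvovirus genome.
merge_ns_vp <- function(prs, nsvp_span_nt, target_seqs = NULL) {
  out <- list()
  for (tid in unique(paste(prs$dataset_id, prs$target_id, sep = "\r"))) {
    key <- strsplit(tid, "\r", fixed = TRUE)[[1]]
    d <- prs[prs$dataset_id == key[1] & prs$target_id == key[2], ,
             drop = FALSE]
    d <- d[stable_order(d$t_beg), , drop = FALSE]
    used <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (used[i]) next
      grp <- i
      if (d$gene_class[i] %in% c("NS", "VP")) {
        for (j in seq_len(nrow(d))) {
          if (j == i || used[j]) next
          if (!(d$gene_class[j] %in% c("NS", "VP"))) next
          if (d$gene_class[j] == d$gene_class[i]) next
          span <- max(d$t_end[c(i, j)]) - min(d$t_beg[c(i, j)])
          if (span <= nsvp_span_nt) grp <- c(grp, j)
        }
      }
      used[grp] <- TRUE
      if (length(grp) == 1) {
        out[[length(out) + 1]] <- d[i, , drop = FALSE]
      } else {
        m <- d[grp[1], , drop = FALSE]
        m$t_beg <- min(d$t_beg[grp]); m$t_end <- max(d$t_end[grp])
        m$gene_class <- "NS_VP"
        if (!is.null(target_seqs) && key[2] %in% names(target_seqs))
          m$seq <- substr(target_seqs[[key[2]]], m$t_beg + 1, m$t_end)
        m$fwd_evalue <- min(d$fwd_evalue[grp])
        m$fwd_score <- max(d$fwd_score[grp])
        m$recip_evalue <- min(d$recip_evalue[grp])
        m$recip_score <- max(d$recip_score[grp])
        bi <- grp[which.min(d$recip_evalue[grp])]
        m$recip_ref_id <- d$recip_ref_id[bi]
        m$ref_genus <- d$ref_genus[bi]
        m$best_reference_identity <- max(d$best_reference_identity[grp])
        # keep the NS peptide (carries the SF3 helicase domain)
        ns <- grp[d$gene_class[grp] == "NS"]
        if (length(ns)) m$peptide <- d$peptide[ns[1]]
        out[[length(out) + 1]] <- m
      }
    }
  }
  do.call(rbind, out)
}
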