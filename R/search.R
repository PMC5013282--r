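# The homology-search engine: exact local alignment plus the seeded
# translated / protein / nucleotide search modes used by every stage.

#' Optimal local alignment of two protein sequences
#'
#' Full Smith-Waterman with affine gaps (gap of length L costs
#' `gap_open + L * gap_extend`). A best score of zero is reported as no hit
#' (`NULL`).
#'
#' @param a,b protein strings.
#' @param scheme a [scoring_scheme()].
#' @return `NULL` or a list with `score`, `a_beg`, `a_end`, `b_beg`, `b_end`
#'   (0-based half-open), `identity`, `aligned_columns` and `cigar`
#'   (`M` aligned pair, `I` gap in `a`, `D` gap in `b`).
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("local_align requires non-empty sequences")
  r <- cpp_sw_align(encode_seq(a, scheme), encode_seq(b, scheme),
                    scheme_matrix_int(scheme), scheme$gap_open,
                    scheme$gap_extend)
  if (r$score <= 0) return(NULL)
  list(score = r$score, a_beg = r$a_beg, a_end = r$a_end, b_beg = r$b_beg,
       b_end = r$b_end, identity = r$n_ident / r$n_cols,
       aligned_columns = r$n_cols, cigar = r$cigar)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), target_id = character(),
             score = integer(), bitscore = numeric(), evalue = numeric(),
             identity = numeric(), aligned_columns = integer(),
             q_beg = integer(), q_end = integer(), t_beg = integer(),
             t_end = integer(), frame = character(), cigar = character(),
             stringsAsFactors = FALSE)
}

# Minimal raw score that can still reach evalue_max; passed to the C++ layer
# so hopeless alignments are not materialised.
min_score_for_evalue <- function(m, n, scheme, evalue_max) {
  if (!is.finite(evalue_max)) return(1L)
  s <- floor(log(scheme$K * m * n / evalue_max) / scheme$lambda)
  if (!is.finite(s)) return(1L)
  max(1L, as.integer(s))
}

finalize_hits <- function(hits, evalue_max) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(empty_hit_table())
  o <- stable_order(hits$evalue, -hits$score, hits$target_id, hits$query_id,
                    hits$t_beg)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Greedy highest-scoring non-overlapping selection per query/target pair.
# Overlap means shared forward-strand target columns, with a one-codon
# tolerance: hits in different frames that abut at a frameshift point share
# up to 3 nt, and both sides of such a break are real.
greedy_nonoverlap <- function(df, tol = 3L) {
  if (nrow(df) <= 1) return(df)
  keep <- logical(nrow(df))
  o <- stable_order(-df$score, df$t_beg, df$q_beg, df$frame)
  taken_beg <- integer(0)
  taken_end <- integer(0)
  for (i in o) {
    if (any(pmin(df$t_end[i], taken_end) -
              pmax(df$t_beg[i], taken_beg) > tol)) next
    keep[i] <- TRUE
    taken_beg <- c(taken_beg, df$t_beg[i])
    taken_end <- c(taken_end, df$t_end[i])
  }
  df[keep, , drop = FALSE]
}

#' Seeded search of protein queries against translated nucleotide targets
#'
#' The tblastn-like mode: every target is translated in six frames and
#' scanned with exact 3-mer amino-acid seeds, X-drop ungapped extension and
#' banded affine-gap extension. Reported hits have
#' `evalue <= evalue_max`; target intervals are 0-based half-open on the
#' forward strand with the frame recorded; overlapping hits on one
#' query-target pair are reduced to the highest-scoring non-overlapping set.
#'
#' @param queries an AA [seq_set()].
#' @param targets an NT [seq_set()].
#' @param scheme a [scoring_scheme()].
#' @param evalue_max E-value cutoff (> 0).
#' @return a hit table (data frame), sorted by (evalue, -score, target_id,
#'   query_id).
#' @export
search_translated <- function(queries, targets, scheme = scoring_scheme(),
                              evalue_max = 1e-3) {
  stopifnot(evalue_max > 0)
  if (!nrow(queries) || !nrow(targets)) return(empty_hit_table())
  frames <- lapply(seq_len(nrow(targets)), function(i)
    translate_six_frames(targets$seq[i]))
  pep <- unlist(lapply(frames, function(fr) lapply(fr, `[[`, "peptide")),
                recursive = FALSE)
  keep <- vapply(pep, nzchar, TRUE)
  meta <- data.frame(
    target = rep(seq_len(nrow(targets)), each = 6),
    frame_i = rep(1:6, nrow(targets)))[keep, , drop = FALSE]
  pep <- pep[keep]
  if (!length(pep)) return(empty_hit_table())
  pep_codes <- lapply(pep, encode_seq, scheme = scheme)
  n_db <- sum(nchar(unlist(pep)))
  n_seqs <- length(pep)
  mat <- scheme_matrix_int(scheme)
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    m <- nchar(queries$seq[qi])
    eff <- effective_mn(m, n_db, n_seqs, scheme)
    smin <- min_score_for_evalue(eff$m, eff$n, scheme, evalue_max)
    gate <- max(scheme$trigger, min(40L, as.integer(0.45 * smin)))
    raw <- cpp_seeded_search(encode_seq(queries$seq[qi], scheme), pep_codes,
                             mat, scheme$gap_open, scheme$gap_extend,
                             scheme$word, scheme$seed_alpha, scheme$xdrop,
                             scheme$trigger, scheme$band_pad, scheme$diag_sep,
                             min(smin, 10000L), gate)
    if (!nrow(raw)) next
    ti <- meta$target[raw$target_idx]
    fr_i <- meta$frame_i[raw$target_idx]
    nt <- t(vapply(seq_len(nrow(raw)), function(r) {
      frame_to_nt_interval(frames[[ti[r]]][[fr_i[r]]], raw$t_beg[r],
                           raw$t_end[r])
    }, integer(2)))
    df <- data.frame(
      query_id = queries$id[qi], target_id = targets$id[ti],
      score = raw$score,
      bitscore = bitscore(raw$score, scheme),
      evalue = evalue(raw$score, eff$m, eff$n, scheme),
      identity = raw$n_ident / raw$n_cols,
      aligned_columns = raw$n_cols,
      q_beg = raw$q_beg, q_end = raw$q_end,
      t_beg = nt[, 1], t_end = nt[, 2],
      frame = vapply(fr_i, function(k) c("+1", "+2", "+3", "-1", "-2", "-3")[k], ""),
      cigar = raw$cigar, stringsAsFactors = FALSE)
    df <- do.call(rbind, lapply(split(df, df$target_id), greedy_nonoverlap))
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) return(empty_hit_table())
  finalize_hits(do.call(rbind, out), evalue_max)
}

#' Seeded protein-protein search
#'
#' The blastp-like mode; same seeding and extension as [search_translated()]
#' but without translation. Both intervals are amino-acid coordinates and
#' the frame is recorded as `"AA"`.
#'
#' @inheritParams search_translated
#' @param targets an AA [seq_set()].
#' @return a hit table.
#' @export
search_protein <- function(queries, targets, scheme = scoring_scheme(),
                           evalue_max = 1e-3) {
  stopifnot(evalue_max > 0)
  if (!nrow(queries) || !nrow(targets)) return(empty_hit_table())
  codes <- lapply(targets$seq, encode_seq, scheme = scheme)
  n_db <- sum(nchar(targets$seq))
  n_seqs <- nrow(targets)
  mat <- scheme_matrix_int(scheme)
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    m <- nchar(queries$seq[qi])
    eff <- effective_mn(m, n_db, n_seqs, scheme)
    smin <- min_score_for_evalue(eff$m, eff$n, scheme, evalue_max)
    gate <- max(scheme$trigger, min(40L, as.integer(0.45 * smin)))
    raw <- cpp_seeded_search(encode_seq(queries$seq[qi], scheme), codes, mat,
                             scheme$gap_open, scheme$gap_extend, scheme$word,
                             scheme$seed_alpha, scheme$xdrop, scheme$trigger,
                             scheme$band_pad, scheme$diag_sep,
                             min(smin, 10000L), gate)
    if (!nrow(raw)) next
    df <- data.frame(
      query_id = queries$id[qi], target_id = targets$id[raw$target_idx],
      score = raw$score, bitscore = bitscore(raw$score, scheme),
      evalue = evalue(raw$score, eff$m, eff$n, scheme),
      identity = raw$n_ident / raw$n_cols, aligned_columns = raw$n_cols,
      q_beg = raw$q_beg, q_end = raw$q_end, t_beg = raw$t_beg,
      t_end = raw$t_end, frame = "AA", cigar = raw$cigar,
      stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) return(empty_hit_table())
  finalize_hits(do.call(rbind, out), evalue_max)
}

#' Seeded nucleotide-nucleotide search
#'
#' The blastn-like mode: exact 11-mer seeds, match +2 / mismatch -3, affine
#' gaps (open 5, extend 2), both strands searched. Minus-strand hits are
#' reported on the forward strand with frame `"NT-"`.
#'
#' @param queries,targets NT [seq_set()]s.
#' @param scheme a [scoring_scheme_nt()].
#' @param evalue_max E-value cutoff (> 0).
#' @return a hit table.
#' @export
search_nucleotide <- function(queries, targets, scheme = scoring_scheme_nt(),
                              evalue_max = 1e-3) {
  stopifnot(evalue_max > 0)
  if (!nrow(queries) || !nrow(targets)) return(empty_hit_table())
  strands <- c("NT+", "NT-")
  seqs <- c(targets$seq, vapply(targets$seq, reverse_complement, ""))
  meta <- data.frame(target = rep(seq_len(nrow(targets)), 2),
                     strand = rep(strands, each = nrow(targets)))
  codes <- lapply(seqs, encode_seq, scheme = scheme)
  n_db <- 2 * sum(nchar(targets$seq))
  n_seqs <- 2L * nrow(targets)
  mat <- scheme_matrix_int(scheme)
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    m <- nchar(queries$seq[qi])
    eff <- effective_mn(m, n_db, n_seqs, scheme)
    smin <- min_score_for_evalue(eff$m, eff$n, scheme, evalue_max)
    gate <- max(scheme$trigger, min(40L, as.integer(0.45 * smin)))
    raw <- cpp_seeded_search(encode_seq(queries$seq[qi], scheme), codes, mat,
                             scheme$gap_open, scheme$gap_extend, scheme$word,
                             scheme$seed_alpha, scheme$xdrop, scheme$trigger,
                             scheme$band_pad, scheme$diag_sep,
                             min(smin, 10000L), gate)
    if (!nrow(raw)) next
    ti <- meta$target[raw$target_idx]
    minus <- meta$strand[raw$target_idx] == "NT-"
    L <- nchar(targets$seq[ti])
    t_beg <- ifelse(minus, L - raw$t_end, raw$t_beg)
    t_end <- ifelse(minus, L - raw$t_beg, raw$t_end)
    df <- data.frame(
      query_id = queries$id[qi], target_id = targets$id[ti],
      score = raw$score, bitscore = bitscore(raw$score, scheme),
      evalue = evalue(raw$score, eff$m, eff$n, scheme),
      identity = raw$n_ident / raw$n_cols, aligned_columns = raw$n_cols,
      q_beg = raw$q_beg, q_end = raw$q_end, t_beg = t_beg, t_end = t_end,
      frame = meta$strand[raw$target_idx], cigar = raw$cigar,
      stringsAsFactors = FALSE)
    df <- do.call(rbind, lapply(split(df, df$target_id), greedy_nonoverlap))
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) return(empty_hit_table())
  finalize_hits(do.call(rbind, out), evalue_max)
}

#' Write a hit table in a blast outfmt-6-like TSV layout
#'
#' Columns, in order: qseqid, sseqid, pident, length, evalue, bitscore,
#' frame, qstart, qend, sstart, send. Exported coordinates are 1-based
#' inclusive (internal tables are 0-based half-open).
#'
#' @param hits a hit table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$target_id,
    pident = round(100 * hits$identity, 2),
    length = hits$aligned_columns,
    evalue = fmt_num(hits$evalue), bitscore = round(hits$bitscore, 1),
    frame = hits$frame,
    qstart = hits$q_beg + 1L, qend = hits$q_end,
    sstart = hits$t_beg + 1L, send = hits$t_end,
    stringsAsFactors = FALSE)
  write_table(df, names(df), path)
}
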