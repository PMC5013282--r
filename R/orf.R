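# Exhaustive six-frame ORF scanning.

#' Find open reading frames in all six frames
#'
#' Exhaustive scan, one call per stop-free codon stretch and frame. A
#' stretch that is preceded by a stop codon (or starts the frame at the 5'
#' sequence edge) and/or terminated by a stop codon yields at most one ORF:
#'
#' * preceded by a stop: the ORF starts at the stretch's first ATG
#'   (no ATG, no call); otherwise (sequence edge) the ORF is 5'-truncated
#'   and starts at the frame's first codon;
#' * terminated by a stop: the ORF ends at (and includes) the stop codon;
#'   otherwise it is 3'-truncated and ends at the frame's last codon.
#'
#' `COMPLETE` therefore means anchored on both sides: starts at an ATG that
#' follows a stop (or scan start after a stop) and ends at a stop. Only ORFs
#' strictly longer than `orf_min_nt` are reported.
#'
#' @param seq nucleotide string or single-row NT [seq_set()].
#' @param orf_min_nt strict minimum length in nucleotides (default 300: an
#'   ORF of exactly 300 nt is excluded).
#' @return data frame with `beg`, `end` (0-based half-open, forward strand),
#'   `strand`, `frame`, `completeness` (`COMPLETE`, `TRUNCATED_5`,
#'   `TRUNCATED_3`, `TRUNCATED_BOTH`) and `peptide` (stop codon excluded).
#' @export
find_orfs <- function(seq, orf_min_nt = 300) {
  s <- if (is.data.frame(seq)) seq$seq[1] else seq
  L <- nchar(s)
  if (L < 3) stop("sequence shorter than 3 nt")
  frames <- translate_six_frames(s)
  out <- list()
  for (fr in frames) {
    pep <- strsplit(fr$peptide, "", fixed = TRUE)[[1]]
    nc <- length(pep)
    if (!nc) next
    stops <- which(pep == "*")
    seg_beg <- c(1L, stops + 1L)
    seg_end_stop <- c(stops, NA) # index of terminating stop codon, NA = edge
    for (k in seq_along(seg_beg)) {
      b <- seg_beg[k]
      stop_at <- seg_end_stop[k]
      e_codon <- if (is.na(stop_at)) nc else stop_at
      if (b > e_codon) next # consecutive stops
      anchored5 <- b > 1L # preceded by a stop codon
      anchored3 <- !is.na(stop_at)
      if (anchored5) {
        last_cand <- e_codon - as.integer(anchored3)
        if (last_cand < b) next
        m_rel <- which(pep[b:last_cand] == "M")
        if (!length(m_rel)) next
        start_codon <- b + m_rel[1] - 1L
      } else {
        start_codon <- b
      }
      if (start_codon > e_codon) next
      len_nt <- (e_codon - start_codon + 1L) * 3L
      if (len_nt <= orf_min_nt) next
      completeness <- if (anchored5 && anchored3) "COMPLETE"
      else if (anchored3) "TRUNCATED_5"
      else if (anchored5) "TRUNCATED_3"
      else "TRUNCATED_BOTH"
      last_pep <- e_codon - as.integer(anchored3)
      pep_out <- if (last_pep >= start_codon)
        paste(pep[start_codon:last_pep], collapse = "") else ""
      nt_iv <- frame_to_nt_interval(fr, start_codon - 1L, e_codon)
      out[[length(out) + 1]] <- data.frame(
        beg = nt_iv[1], end = nt_iv[2], strand = fr$strand,
        frame = fr$frame, completeness = completeness, peptide = pep_out,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(beg = integer(), end = integer(), strand = character(),
                      frame = character(), completeness = character(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[stable_order(res$beg, res$end, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}
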