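# Six-frame translation with coordinate bookkeeping. Translation is a
# vectorised codon-table lookup (cheap for the many short sequences the
# search engine translates); the table itself is the standard genetic code.

genetic_code_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) map <<- Biostrings::GENETIC_CODE
    map
  }
})

#' Reverse complement of a nucleotide string
#'
#' @param s nucleotide string (ACGTN).
#' @return the reverse complement string.
#' @export
reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s))))
}

# translate an in-frame nucleotide string (length trimmed to a codon
# multiple); stops emit '*', codons containing N emit 'X'
translate_nt <- function(s) {
  L <- (nchar(s) %/% 3) * 3
  if (L < 3) return("")
  starts <- seq.int(1, L - 2, by = 3)
  codons <- substring(s, starts, starts + 2)
  aa <- genetic_code_map()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; stop codons emit `*`; any codon containing `N`
#' emits `X`. Reverse frames are translated on the reverse complement; their
#' peptide positions map back to forward-strand coordinates through
#' [frame_to_nt_interval()].
#'
#' @param seq a nucleotide string or a single-row NT [seq_set()].
#' @return list of six frames, each a list with `frame` (one of `"+1"`,
#'   `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`), `phase` (0-2), `strand`,
#'   `peptide`, and `nt_len` (length of the source sequence).
#' @export
translate_six_frames <- function(seq) {
  s <- if (is.data.frame(seq)) seq$seq[1] else seq
  L <- nchar(s)
  if (L < 3) stop("sequence shorter than 3 nt cannot be translated")
  rc <- reverse_complement(s)
  out <- vector("list", 6)
  k <- 0
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else rc
    for (phase in 0:2) {
      k <- k + 1
      pep <- translate_nt(substr(src, phase + 1, L))
      out[[k]] <- list(frame = paste0(strand, phase + 1), phase = phase,
                       strand = strand, peptide = pep, nt_len = L)
    }
  }
  out
}

#' Map a frame-peptide interval to forward-strand nucleotide coordinates
#'
#' @param frame one frame entry from [translate_six_frames()], or a frame
#'   label plus `nt_len`.
#' @param beg,end 0-based half-open interval on the frame's peptide.
#' @param nt_len source sequence length (only needed when `frame` is a label).
#' @return integer vector `c(beg, end)`: 0-based half-open forward-strand
#'   nucleotide interval.
#' @export
frame_to_nt_interval <- function(frame, beg, end, nt_len = NULL) {
  if (is.list(frame)) {
    lab <- frame$frame
    L <- frame$nt_len
  } else {
    lab <- frame
    L <- nt_len
  }
  phase <- as.integer(substr(lab, 2, 2)) - 1L
  if (substr(lab, 1, 1) == "+") {
    c(phase + 3L * beg, phase + 3L * end)
  } else {
    c(L - phase - 3L * end, L - phase - 3L * beg)
  }
}
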