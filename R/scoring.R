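# Scoring schemes and Karlin-Altschul statistics.

#' Protein scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used for E-values. The default mirrors the
#' conventional translated-search setup: BLOSUM62 with gap open 11 / extend 1
#' and the matching gapped parameters lambda = 0.267, K = 0.041. A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix `"BLOSUM62"` (the only named preset) or a symmetric integer
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend non-negative integers, `gap_extend <= gap_open`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("unknown matrix preset: ", matrix)
    mat <- get_blosum62()
  } else {
    mat <- as.matrix(matrix)
  }
  letters <- AA_ALPHABET
  miss <- setdiff(letters, rownames(mat))
  if (length(miss)) stop("substitution matrix lacks rows for: ",
                         paste(miss, collapse = ", "))
  mat <- mat[letters, letters]
  if (!isTRUE(all.equal(mat, t(mat)))) stop("substitution matrix must be symmetric")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(kind = "AA", matrix = mat, letters = letters,
                 seed_alpha = 20L, word = 3L,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, H = 0.14,
                 xdrop = 16L, trigger = 16L, band_pad = 32L, diag_sep = 64L),
            class = "scoring_scheme")
}

#' Nucleotide scoring scheme
#'
#' Match/mismatch scoring over ACGTN (N scores 0 against everything) with
#' affine gaps; defaults follow the common megablast-style parameterisation
#' match +2 / mismatch -3, gap open 5 / extend 2, with the matching
#' Karlin-Altschul parameters lambda = 0.625, K = 0.41.
#'
#' @param match,mismatch integer match reward and mismatch penalty.
#' @param gap_open,gap_extend non-negative integers.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme_nt <- function(match = 2, mismatch = -3, gap_open = 5,
                              gap_extend = 2, lambda = 0.625, K = 0.41) {
  letters <- NT_ALPHABET
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- 0L
  mat[, "N"] <- 0L
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  structure(list(kind = "NT", matrix = mat, letters = letters,
                 seed_alpha = 4L, word = 11L,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, H = 1.1,
                 xdrop = 20L, trigger = 22L, band_pad = 24L, diag_sep = 48L),
            class = "scoring_scheme")
}

# Standard BLOSUM62 (quarter-bit units) as shipped with Biostrings.
get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` between a length-`m` query and a
#' database of total length `n`.
#'
#' @param score raw alignment score (non-negative).
#' @param m query length.
#' @param n total database length.
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return numeric E-value(s).
#' @export
evalue <- function(score, m, n, scheme) {
  stopifnot(all(score >= 0), all(m >= 1), all(n >= 1))
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Bit score
#'
#' `(lambda * score - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return numeric bit score(s).
#' @export
bitscore <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

# Integer-encode residues for the C++ kernels (0-based; NA is an error).
encode_seq <- function(s, scheme) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt(paste(scheme$letters, collapse = "")) + 1L] <-
    seq_along(scheme$letters) - 1L
  codes <- lut[as.integer(charToRaw(s)) + 1L]
  if (anyNA(codes)) {
    p <- which(is.na(codes))[1]
    stop("residue not in scoring alphabet at position ", p, ": ",
         substr(s, p, p))
  }
  codes
}

# Finite-length ("edge effect") adjustment used by the search stages: short
# sequences cannot host alignments near their ends, so the effective search
# space is smaller than m * n. The adjustment length solves
# l = ln(K * (m - l) * (n - N * l)) / H by fixed-point iteration, as in the
# standard database-search practice. The bare evalue() operation stays the
# unadjusted formula.
effective_mn <- function(m, n, n_seqs, scheme) {
  l <- 0
  for (it in 1:5) {
    me <- max(m - l, 1 / scheme$K)
    ne <- max(n - n_seqs * l, 1 / scheme$K)
    l2 <- max(0, log(scheme$K * me * ne) / scheme$H)
    if (abs(l2 - l) < 0.5) { l <- l2; break }
    l <- l2
  }
  list(m = max(m - l, 1 / scheme$K), n = max(n - n_seqs * l, 1 / scheme$K))
}

scheme_matrix_int <- function(scheme) {
  m <- scheme$matrix
  storage.mode(m) <- "integer"
  m
}
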