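# Stage 4: SF3 helicase domain extraction, progressive MSA, NJ + bootstrap.

#' Extract an SF3 helicase domain fragment from a protein
#'
#' Aligns the protein locally against every reference SF3 fragment; if the
#' best score reaches `min_score` the aligned region of the protein is
#' returned, extended (or clipped) symmetrically to at most `window`
#' residues around the aligned core. The default `min_score` is the score
#' at which the expected number of chance matches against the reference set
#' is `fp_rate` (the pipeline-wide E-value philosophy).
#'
#' @param protein protein string or single-row AA [seq_set()].
#' @param sf3_refs AA [seq_set()] of reference SF3 fragments.
#' @param window fragment length cap in residues (default 191).
#' @param scheme protein [scoring_scheme()].
#' @param min_score minimum best local score; `NULL` = derive from
#'   `fp_rate`.
#' @param fp_rate expected chance-match rate fixing the default score
#'   threshold (default `1e-3`).
#' @return `NULL`, or a list with `fragment`, `frag_beg`, `frag_end`
#'   (0-based half-open on the protein), `best_ref` and `score`.
#' @export
extract_sf3 <- function(protein, sf3_refs, window = 191,
                        scheme = scoring_scheme(), min_score = NULL,
                        fp_rate = 1e-3) {
  if (!nrow(sf3_refs)) stop("sf3_refs must be non-empty")
  p <- if (is.data.frame(protein)) protein$seq[1] else protein
  if (is.null(min_score)) {
    n_db <- sum(nchar(sf3_refs$seq))
    min_score <- ceiling(log(scheme$K * nchar(p) * n_db / fp_rate) /
                           scheme$lambda)
  }
  best <- NULL
  for (i in seq_len(nrow(sf3_refs))) {
    al <- local_align(p, sf3_refs$seq[i], scheme)
    if (is.null(al)) next
    if (is.null(best) || al$score > best$score) {
      best <- al
      best$ref <- sf3_refs$id[i]
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  b <- best$a_beg
  e <- best$a_end
  core_len <- e - b
  if (core_len > window) { # clip to the window, centred on the core
    trim <- core_len - window
    b <- b + trim %/% 2
    e <- b + window
  } else if (core_len < window) { # extend symmetrically within the protein
    pad <- window - core_len
    b <- max(0, b - pad %/% 2)
    e <- min(nchar(p), b + window)
    b <- max(0, e - window)
  }
  list(fragment = substr(p, b + 1, e), frag_beg = b, frag_end = e,
       best_ref = best$ref, score = best$score)
}

# 3-mer fractional-common-kmer distance between two sequences.
kmer_distance_matrix <- function(seqs, k = 3) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character()))
    table(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) next
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      common <- sum(pmin(ci[shared], cj[shared]))
      denom <- max(1, min(sum(ci), sum(cj)))
      d[i, j] <- d[j, i] <- 1 - common / denom
    }
  }
  d
}

msa_letters <- function() AA_ALPHABET

# Column frequency profile over the residue alphabet plus gap (last row).
seq_profile <- function(gapped) {
  letters <- msa_letters()
  n <- length(letters)
  chars <- strsplit(gapped[1], "", fixed = TRUE)[[1]]
  L <- length(chars)
  P <- matrix(0, n + 1, L)
  for (s in gapped) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(ch, c(letters, "-"))
    P[cbind(idx, seq_len(L))] <- P[cbind(idx, seq_len(L))] + 1
  }
  P / length(gapped)
}

apply_path <- function(gapped, path) {
  idx <- ifelse(path == 0, NA_integer_, path)
  chars <- lapply(gapped, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  vapply(chars, function(ch) {
    out <- ch[idx]
    out[is.na(out)] <- "-"
    paste(out, collapse = "")
  }, "")
}

#' Progressive multiple sequence alignment
#'
#' Single-pass progressive alignment: 3-mer fractional-common-kmer
#' distances, a UPGMA guide tree, then profile-profile alignment with
#' sum-of-pairs scoring (affine gaps, end gaps free). Deterministic under a
#' fixed input order; ungapping any output row reproduces its input
#' sequence exactly.
#'
#' @param fragments AA [seq_set()] with at least 2 rows and unique ids.
#' @param scheme protein [scoring_scheme()].
#' @return an `msa`: list with `ids` and `aln` (named character vector of
#'   equal-length gapped rows, input order).
#' @export
progressive_msa <- function(fragments, scheme = scoring_scheme()) {
  if (nrow(fragments) < 2) stop("progressive_msa needs at least 2 fragments")
  if (anyDuplicated(fragments$id)) stop("duplicate fragment ids")
  n <- nrow(fragments)
  D <- kmer_distance_matrix(fragments$seq)
  hc <- hclust(as.dist(D), method = "average")
  B <- scheme$matrix[msa_letters(), msa_letters()]
  aligned <- as.list(fragments$seq)
  node_block <- vector("list", nrow(hc$merge))
  for (step in seq_len(nrow(hc$merge))) {
    left <- hc$merge[step, 1]
    right <- hc$merge[step, 2]
    mem_l <- if (left < 0) -left else node_block[[left]]
    mem_r <- if (right < 0) -right else node_block[[right]]
    g1 <- unlist(aligned[mem_l])
    g2 <- unlist(aligned[mem_r])
    P1 <- seq_profile(g1)
    P2 <- seq_profile(g2)
    nl <- length(msa_letters())
    sim <- t(P1[seq_len(nl), , drop = FALSE]) %*% B %*%
      P2[seq_len(nl), , drop = FALSE]
    path <- cpp_nw_profile(sim, scheme$gap_open, scheme$gap_extend, TRUE)
    new_l <- apply_path(g1, path$path1)
    new_r <- apply_path(g2, path$path2)
    aligned[mem_l] <- as.list(new_l)
    aligned[mem_r] <- as.list(new_r)
    node_block[[step]] <- c(mem_l, mem_r)
  }
  aln <- unlist(aligned)
  names(aln) <- fragments$id
  structure(list(ids = fragments$id, aln = aln), class = "msa")
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$aln), "", fixed = TRUE))
}

#' Pairwise p-distance matrix from an alignment
#'
#' `d(i, j)` = mismatches / columns where neither row is gapped (pairwise
#' deletion). A pair with zero comparable columns is an error by default;
#' `on_empty = "max"` substitutes the largest finite distance in the matrix
#' (used inside bootstrap replicates, where column resampling can remove
#' all shared columns of a divergent pair).
#'
#' @param msa an `msa` (or named character vector of gapped rows).
#' @param on_empty `"error"` or `"max"`.
#' @return symmetric numeric matrix with row/col names.
#' @export
p_distance_matrix <- function(msa, on_empty = c("error", "max")) {
  on_empty <- match.arg(on_empty)
  aln <- if (inherits(msa, "msa")) msa$aln else msa
  if (length(aln) < 2) stop("need at least 2 rows")
  M <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(M) <- names(aln)
  pdist_from_matrix(M, on_empty)
}

pdist_from_matrix <- function(M, on_empty = "error") {
  n <- nrow(M)
  gap <- M == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  empty <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        empty <- rbind(empty, c(i, j))
        d[i, j] <- d[j, i] <- NA
        next
      }
      mm <- sum(M[i, comp] != M[j, comp])
      d[i, j] <- d[j, i] <- mm / nc
    }
  }
  if (!is.null(empty)) {
    if (on_empty == "error")
      stop("no comparable columns between rows ", rownames(M)[empty[1, 1]],
           " and ", rownames(M)[empty[1, 2]])
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix (delegated to
#' the standard implementation in \pkg{ape}); negative branch lengths are
#' clamped to zero.
#'
#' @param d symmetric distance matrix with dimnames (>= 3 taxa).
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support by column resampling
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times, rebuilds a tree
#' per replicate, and sets each internal edge's support to the fraction of
#' replicate trees containing its bipartition. Seeded and reproducible.
#'
#' @param msa an `msa`.
#' @param replicates number of replicates (default 500).
#' @param seed integer seed.
#' @return the reference `phylo` tree with `node.label` carrying supports in
#'   `[0, 1]` (root label empty).
#' @export
bootstrap_support <- function(msa, replicates = 500, seed = 1) {
  stopifnot(replicates >= 1)
  M <- msa_matrix(msa)
  rownames(M) <- msa$ids
  ref <- nj_tree(p_distance_matrix(msa))
  trees <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      nj_tree(pdist_from_matrix(M[, cols, drop = FALSE], on_empty = "max"))
    })
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / replicates
  ref$node.label <- formatC(support, digits = 3, format = "f")
  ref$node.label[1] <- "" # root of the unrooted representation
  attr(ref, "support") <- support
  ref
}

#' Root a tree on its outgroup
#'
#' Roots on the outgroup's pendant edge; supports (node labels) stay
#' attached to the edges they belong to, so ingroup bipartitions and their
#' supports are unchanged.
#'
#' @param tree a `phylo` tree with `node.label` supports.
#' @param outgroup_id a leaf id.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup leaf not in tree: ", outgroup_id)
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Report well-supported single-phylum clades containing PRSs
#'
#' Every maximal clade with support strictly greater than `support_min`
#' whose leaves all share one host phylum and include at least one PRS.
#'
#' @param tree rooted `phylo` tree with supports as node labels.
#' @param phylum named character vector: leaf id to host phylum.
#' @param is_prs named logical vector: leaf id to PRS flag.
#' @param support_min strict support threshold (default 0.70: a clade at
#'   exactly 0.70 is excluded).
#' @return data frame `phylum`, `n_leaves`, `n_prs`, `support`, `leaves`.
#' @export
annotate_clades <- function(tree, phylum, is_prs, support_min = 0.70) {
  nt <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  support <- suppressWarnings(as.numeric(tree$node.label))
  cand <- list()
  for (k in seq_along(parts)) {
    if (k == 1) next # the root (all leaves)
    sup <- support[k]
    if (is.na(sup) || sup <= support_min) next
    leaves <- tree$tip.label[parts[[k]]]
    ph <- unique(phylum[leaves])
    if (length(ph) != 1 || is.na(ph)) next
    if (!any(is_prs[leaves], na.rm = TRUE)) next
    cand[[length(cand) + 1]] <- list(leaves = leaves, support = sup,
                                     phylum = ph)
  }
  if (!length(cand)) {
    return(data.frame(phylum = character(), n_leaves = integer(),
                      n_prs = integer(), support = numeric(),
                      leaves = character(), stringsAsFactors = FALSE))
  }
  # maximal: drop clades nested inside another reported clade
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i != j && keep[j] &&
          all(cand[[i]]$leaves %in% cand[[j]]$leaves) &&
          length(cand[[i]]$leaves) < length(cand[[j]]$leaves)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cand <- cand[keep]
  out <- data.frame(
    phylum = vapply(cand, `[[`, "", "phylum"),
    n_leaves = vapply(cand, function(x) length(x$leaves), 1L),
    n_prs = vapply(cand, function(x) sum(is_prs[x$leaves], na.rm = TRUE), 1L),
    support = vapply(cand, `[[`, 0, "support"),
    leaves = vapply(cand, function(x)
      paste(sort(x$leaves), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[stable_order(out$phylum, -out$n_leaves, out$leaves), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an alignment in FASTA or relaxed PHYLIP
#'
#' @param msa an `msa`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta(seq_set_gapped(msa), path)
}

#' @rdname write_msa_fasta
#' @export
write_msa_phylip <- function(msa, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(msa$aln), nchar(msa$aln[[1]])), con)
  writeLines(paste(names(msa$aln), unname(msa$aln)), con)
  invisible(path)
}

# gapped rows bypass residue validation
seq_set_gapped <- function(msa) {
  out <- data.frame(id = names(msa$aln), desc = "", seq = unname(msa$aln),
                    stringsAsFactors = FALSE)
  attr(out, "moltype") <- "AA"
  class(out) <- c("seq_set", "data.frame")
  out
}
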