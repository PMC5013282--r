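# Stage 3: identity binning, origin assignment, contamination triage.

#' Bin a best-reference identity
#'
#' Bins follow the reported identity structure of PRSs and the ICTV genus
#' demarcation (> 30% NS1 amino-acid identity): `[0, 0.30)` NOVEL_LINEAGE,
#' `[0.30, 0.85]` INTERMEDIATE, `(0.85, 1]` KNOWN_VIRUS_LIKE. Both
#' boundaries fall into the middle bin.
#'
#' @param best_reference_identity fraction in `[0, 1]` (vectorised).
#' @return character vector of bin labels.
#' @export
identity_bin <- function(best_reference_identity) {
  x <- best_reference_identity
  if (any(is.na(x)) || any(x < 0 | x > 1))
    stop("identity must be in [0, 1]")
  ifelse(x < 0.30, "NOVEL_LINEAGE",
         ifelse(x <= 0.85, "INTERMEDIATE", "KNOWN_VIRUS_LIKE"))
}

#' Assign an origin from an evidence bundle
#'
#' Priority-ordered rules: (a) a genomic match plus degradation evidence
#' (internal stops, frameshift or TE flank) is ENDOGENOUS_DEGRADED; (b) a
#' genomic match plus intact NS+VP is ENDOGENOUS_INTACT; (c) a genomic match
#' without either is AMBIGUOUS; (d) no genomic match is EXTANT_CANDIDATE.
#' A match sitting at a scaffold edge forces AMBIGUOUS unless rule (a)
#' already fired. Degraded takes priority over intact so mixed evidence is
#' read as degradation.
#'
#' @param ev one evidence row ([gather_evidence()]).
#' @return list with `origin` and `rationale` (rule ids fired).
#' @export
assign_origin <- function(ev) {
  fired <- character()
  has_match <- ev$n_genomic_matches >= 1
  degraded <- isTRUE(ev$internal_stop_count >= 1) ||
    isTRUE(ev$frameshift_suspected) || isTRUE(ev$te_flank_5) ||
    isTRUE(ev$te_flank_3)
  if (has_match && degraded) {
    fired <- c(fired, "origin:degraded")
    return(list(origin = "ENDOGENOUS_DEGRADED", rationale = fired))
  }
  if (has_match && isTRUE(ev$at_scaffold_edge)) {
    return(list(origin = "AMBIGUOUS", rationale = "origin:scaffold_edge"))
  }
  if (has_match && isTRUE(ev$intact_ns_vp)) {
    return(list(origin = "ENDOGENOUS_INTACT", rationale = "origin:intact"))
  }
  if (has_match) {
    return(list(origin = "AMBIGUOUS", rationale = "origin:match_only"))
  }
  list(origin = "EXTANT_CANDIDATE", rationale = "origin:no_genomic_match")
}

# Lineage compatibility at a taxonomic rank. Lineages are ordered
# semicolon-joined taxon lists (kingdom first). Disjointness is evaluated at
# `rank` (1-based position; default 2 = phylum); when both lineages agree at
# the rank on Chordata the comparison moves one rank down (class), mirroring
# how mammal-infecting viruses in amphibian datasets are treated as
# incompatible despite the shared phylum.
lineage_compatible <- function(virus_lineage, host_lineage, rank = 2,
                               chordata_class_rule = TRUE) {
  if (is.na(virus_lineage) || is.na(host_lineage) ||
      !nzchar(virus_lineage) || !nzchar(host_lineage)) return(NA)
  v <- strsplit(virus_lineage, ";", fixed = TRUE)[[1]]
  h <- strsplit(host_lineage, ";", fixed = TRUE)[[1]]
  if (length(v) < rank || length(h) < rank) return(NA)
  if (v[rank] != h[rank]) return(FALSE)
  if (chordata_class_rule && identical(v[rank], "Chordata")) {
    if (length(v) < rank + 1 || length(h) < rank + 1) return(NA)
    return(v[rank + 1] == h[rank + 1])
  }
  TRUE
}

#' Contamination triage for one PRS
#'
#' A PRS is flagged as a suspected contaminant iff it is KNOWN_VIRUS_LIKE
#' (> 85% identity to a panel protein) and the known host lineage of its
#' best reciprocal reference shares no taxon with the dataset's host lineage
#' at the configured rank (phylum by default; class within Chordata).
#'
#' @param prs one PRS row.
#' @param bin the PRS's identity bin.
#' @param panel reference panel (source of `known_host_lineage`).
#' @param dataset_lineage the dataset's host lineage string.
#' @param rank taxonomic rank position used for the disjointness test
#'   (default 2 = phylum).
#' @return TRUE / FALSE / NA (NA = lineage unevaluable).
#' @export
contamination_triage <- function(prs, bin, panel, dataset_lineage, rank = 2) {
  if (bin != "KNOWN_VIRUS_LIKE") return(FALSE)
  ann <- panel$annotations[panel$annotations$id == prs$recip_ref_id, ]
  if (!nrow(ann)) return(NA)
  compat <- lineage_compatible(ann$host_lineage, dataset_lineage, rank = rank)
  if (is.na(compat)) return(NA)
  !compat
}

#' Classify every PRS
#'
#' Pure function of the PRS table, evidence bundle, panel and dataset
#' lineages: assigns the identity bin, origin and contaminant flag with the
#' list of rules that fired.
#'
#' @param prs_table PRS table.
#' @param evidence evidence table ([gather_evidence()]).
#' @param panel reference panel.
#' @param manifest dataset manifest (for host lineages).
#' @param rank contamination rank (default 2 = phylum).
#' @return labels data frame.
#' @export
classify_prs <- function(prs_table, evidence, panel, manifest, rank = 2) {
  out <- lapply(seq_len(nrow(prs_table)), function(i) {
    prs <- prs_table[i, ]
    ev <- evidence[evidence$prs_id == prs$prs_id, ]
    if (!nrow(ev)) stop("no evidence row for ", prs$prs_id)
    bin <- identity_bin(prs$best_reference_identity)
    org <- assign_origin(ev)
    lin <- manifest$host_lineage[manifest$dataset_id == prs$dataset_id]
    lin <- if (length(lin)) lin[1] else prs$host_lineage
    cont <- contamination_triage(prs, bin, panel, lin, rank = rank)
    rat <- c(paste0("bin:", bin), org$rationale,
             if (isTRUE(cont)) "contaminant:lineage_incompatible")
    data.frame(prs_id = prs$prs_id, identity_bin = bin, origin = org$origin,
               contaminant_suspect = cont,
               rationale = paste(rat, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(prs_id = character(), identity_bin = character(),
                      origin = character(), contaminant_suspect = logical(),
                      rationale = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Summary tables over classified PRSs
#'
#' Deterministic count tables: per dataset, per host phylum, identity-bin
#' proportions and origin counts; contaminant-flagged PRSs are tabulated
#' separately (discarded).
#'
#' @param labels labels table ([classify_prs()]).
#' @param prs_table PRS table.
#' @param manifest dataset manifest.
#' @return list of data frames: `by_dataset`, `by_phylum`, `by_bin`,
#'   `by_origin`, `discarded`.
#' @export
summarize_labels <- function(labels, prs_table, manifest) {
  if (nrow(labels) && !all(labels$prs_id %in% prs_table$prs_id))
    stop("label with unknown prs_id")
  m <- merge(labels, prs_table[, c("prs_id", "dataset_id", "gene_class",
                                   "host_lineage")], by = "prs_id")
  m$phylum <- vapply(strsplit(m$host_lineage, ";", fixed = TRUE),
                     function(x) if (length(x) >= 2) x[2] else NA_character_,
                     "")
  disc <- m[isTRUE_vec(m$contaminant_suspect), , drop = FALSE]
  keep <- m[!isTRUE_vec(m$contaminant_suspect), , drop = FALSE]
  count_by <- function(d, key) {
    if (!nrow(d)) return(data.frame(key = character(), n = integer(),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))
    tb <- table(d[[key]])
    data.frame(key = names(tb), n = as.integer(tb), stringsAsFactors = FALSE)
  }
  by_dataset <- count_by(keep, "dataset_id")
  names(by_dataset)[1] <- "dataset_id"
  by_phylum <- count_by(keep, "phylum")
  names(by_phylum)[1] <- "phylum"
  by_bin <- count_by(keep, "identity_bin")
  names(by_bin)[1] <- "identity_bin"
  by_bin$proportion <- if (nrow(by_bin)) by_bin$n / sum(by_bin$n) else numeric()
  by_origin <- count_by(keep, "origin")
  names(by_origin)[1] <- "origin"
  disc_out <- disc[stable_order(disc$prs_id),
                   c("prs_id", "dataset_id", "identity_bin", "origin",
                     "rationale"), drop = FALSE]
  rownames(disc_out) <- NULL
  list(by_dataset = by_dataset, by_phylum = by_phylum, by_bin = by_bin,
       by_origin = by_origin, discarded = disc_out)
}

isTRUE_vec <- function(x) !is.na(x) & x
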