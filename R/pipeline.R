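# Pipeline orchestration: configuration, staged execution, artifacts.

#' Pipeline configuration
#'
#' Defaults are the analysis cutoffs: forward and reciprocal E-value 1e-3;
#' genomic cross-reference identity 0.95 at E-value 1e-5; 500-nt flank
#' window; ORFs strictly longer than 300 nt; identity bins at 0.30 / 0.85;
#' contamination identity 0.85; 191-aa SF3 window; 500 bootstrap
#' replicates; clade support strictly above 0.70. Overrides are echoed into
#' the run manifest.
#'
#' @param panel_fasta,panel_annotations reference panel inputs.
#' @param manifest dataset manifest TSV path.
#' @param decoys_fasta decoy protein FASTA for reciprocal confirmation.
#' @param te_library_fasta optional TE library FASTA (`NULL` = unscanned).
#' @param sf3_refs_fasta optional reference SF3 fragments FASTA (`NULL`
#'   skips the phylogeny stage).
#' @param out_dir run directory.
#' @param seed top-level seed fanned out to the stochastic stages.
#' @param ... threshold overrides: `forward_evalue`, `reciprocal_evalue`,
#'   `genomic_identity`, `genomic_evalue`, `flank_window`, `orf_min_nt`,
#'   `bin_low`, `bin_high`, `contamination_identity`, `contamination_rank`,
#'   `sf3_window`, `bootstrap`, `support_min`, `locus_gap_nt`,
#'   `nsvp_span_nt`, `frameshift_margin`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel_fasta = NULL, panel_annotations = NULL,
                            manifest = NULL, decoys_fasta = NULL,
                            te_library_fasta = NULL, sf3_refs_fasta = NULL,
                            out_dir = NULL, seed = 1L, ...) {
  cfg <- list(
    panel_fasta = panel_fasta, panel_annotations = panel_annotations,
    manifest = manifest, decoys_fasta = decoys_fasta,
    te_library_fasta = te_library_fasta, sf3_refs_fasta = sf3_refs_fasta,
    out_dir = out_dir, seed = as.integer(seed),
    forward_evalue = 1e-3, reciprocal_evalue = 1e-3,
    genomic_identity = 0.95, genomic_evalue = 1e-5,
    flank_window = 500L, orf_min_nt = 300L,
    bin_low = 0.30, bin_high = 0.85,
    contamination_identity = 0.85, contamination_rank = 2L,
    sf3_window = 191L, bootstrap = 500L, support_min = 0.70,
    locus_gap_nt = 300L, nsvp_span_nt = 6000L, frameshift_margin = 15L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline option: ", bad[1])
  cfg[names(over)] <- over
  cfg$overrides <- names(over)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order — forward search, reciprocal confirmation,
#' endogenization evidence, classification, SF3 phylogeny, summaries — and
#' writes every report into `config$out_dir`. Identical inputs and config
#' produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- load_reference_panel(config$panel_fasta, config$panel_annotations)
  manifest <- read_dataset_manifest(config$manifest)
  decoys <- read_fasta(config$decoys_fasta, "AA")
  te_library <- if (!is.null(config$te_library_fasta))
    read_fasta(config$te_library_fasta, "NT")
  else seq_set(character(), character(), moltype = "NT")
  scheme <- scoring_scheme()

  # stage 1: forward search + reciprocal confirmation, per dataset
  all_hits <- list()
  all_prs <- list()
  for (i in seq_len(nrow(manifest))) {
    ds <- manifest[i, ]
    targets <- read_fasta(ds$path, if (ds$kind == "PROTEIN") "AA" else "NT")
    hits <- forward_search(panel, ds, evalue_max = config$forward_evalue,
                           scheme = scheme, targets = targets)
    if (nrow(hits)) all_hits[[length(all_hits) + 1]] <- hits
    prs <- reciprocal_confirm(hits, panel, decoys, targets, ds,
                              evalue_max = config$reciprocal_evalue,
                              scheme = scheme,
                              locus_gap_nt = config$locus_gap_nt,
                              nsvp_span_nt = config$nsvp_span_nt)
    if (nrow(prs)) all_prs[[length(all_prs) + 1]] <- prs
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    cbind(dataset_id = character(0), empty_hit_table())
  prs <- if (length(all_prs)) do.call(rbind, all_prs) else prs_empty()
  if (nrow(prs)) { # re-key PRS ids across datasets
    prs <- prs[stable_order(prs$dataset_id, prs$target_id, prs$t_beg), ,
               drop = FALSE]
    prs$prs_id <- sprintf("PRS%04d", seq_len(nrow(prs)))
    rownames(prs) <- NULL
  }

  # stage 2: endogenization evidence
  genomes <- load_genome_datasets(manifest)
  evb <- gather_evidence(prs, genomes, te_library, panel, config)

  # stage 3: classification + summaries
  labels <- classify_prs(prs, evb$evidence, panel, manifest,
                         rank = config$contamination_rank)
  summaries <- summarize_labels(labels, prs, manifest)

  # stage 4: SF3 phylogeny
  phylo <- NULL
  if (!is.null(config$sf3_refs_fasta)) {
    sf3_refs <- read_fasta(config$sf3_refs_fasta, "AA")
    phylo <- run_sf3_phylogeny(prs, labels, sf3_refs, panel, manifest,
                               config)
  }

  paths <- write_run_artifacts(config, panel, manifest, hits, prs, evb,
                               labels, summaries, phylo)
  invisible(list(panel = panel, manifest = manifest, hits = hits, prs = prs,
                 evidence = evb$evidence, matches = evb$matches,
                 labels = labels, summaries = summaries, phylo = phylo,
                 paths = paths))
}

#' SF3 phylogeny stage
#'
#' Extracts SF3 fragments from NS-bearing PRS peptides, aligns them together
#' with the reference fragments, builds the bootstrapped NJ tree, roots it
#' on the outgroup fragment when present, and reports well-supported
#' single-phylum PRS clades.
#'
#' @param prs PRS table.
#' @param labels labels table (contaminant-flagged PRSs are excluded).
#' @param sf3_refs reference SF3 fragments (AA [seq_set()]); an id ending in
#'   `outgroupD5_sf3` (or matching the panel outgroup) is used for rooting.
#' @param panel reference panel.
#' @param manifest dataset manifest.
#' @param config a [pipeline_config()].
#' @return `NULL` (fewer than 4 alignable rows) or a list with `msa`,
#'   `tree`, `clades` and `fragments`.
#' @export
run_sf3_phylogeny <- function(prs, labels, sf3_refs, panel, manifest,
                              config = pipeline_config()) {
  keep <- merge(prs, labels, by = "prs_id")
  keep <- keep[!isTRUE_vec(keep$contaminant_suspect) &
                 keep$gene_class %in% c("NS", "NS_VP"), , drop = FALSE]
  frags <- list()
  for (i in seq_len(nrow(keep))) {
    pep <- gsub("[*X]", "X", keep$peptide[i])
    if (nchar(pep) < 30) next
    hit <- extract_sf3(pep, sf3_refs, window = config$sf3_window)
    if (is.null(hit)) next
    frags[[length(frags) + 1]] <- data.frame(
      id = keep$prs_id[i], seq = hit$fragment, dataset_id = keep$dataset_id[i],
      stringsAsFactors = FALSE)
  }
  prs_frag <- if (length(frags)) do.call(rbind, frags) else NULL
  rows <- data.frame(
    id = c(sf3_refs$id, if (!is.null(prs_frag)) prs_frag$id),
    seq = c(sf3_refs$seq, if (!is.null(prs_frag)) prs_frag$seq),
    stringsAsFactors = FALSE)
  if (nrow(rows) < 4) return(NULL)
  fragments <- seq_set(rows$id, rows$seq, moltype = "AA")
  msa <- progressive_msa(fragments)
  tree <- bootstrap_support(msa, replicates = config$bootstrap,
                            seed = derive_seed(config$seed, 7L))
  og <- panel_outgroup_id(panel)
  og_leaf <- if (!is.na(og)) {
    cand <- tree$tip.label[tree$tip.label %in%
                             c(og, paste0(og, "_sf3"))]
    if (length(cand)) cand[1] else NA_character_
  } else NA_character_
  if (!is.na(og_leaf)) tree <- root_with_outgroup(tree, og_leaf)
  # leaf -> host phylum (PRS leaves) or virus host phylum (panel leaves)
  phylum <- setNames(rep(NA_character_, length(tree$tip.label)),
                     tree$tip.label)
  ann <- panel$annotations
  for (leaf in tree$tip.label) {
    pid <- sub("_sf3$", "", leaf)
    if (pid %in% ann$id) {
      lin <- ann$host_lineage[ann$id == pid]
      phylum[leaf] <- if (nzchar(lin))
        strsplit(lin, ";", fixed = TRUE)[[1]][2] else NA_character_
    } else if (!is.null(prs_frag) && leaf %in% prs_frag$id) {
      ds <- prs_frag$dataset_id[prs_frag$id == leaf]
      lin <- manifest$host_lineage[manifest$dataset_id == ds]
      phylum[leaf] <- strsplit(lin[1], ";", fixed = TRUE)[[1]][2]
    }
  }
  is_prs <- setNames(grepl("^PRS", tree$tip.label), tree$tip.label)
  clades <- annotate_clades(tree, phylum, is_prs,
                            support_min = config$support_min)
  list(msa = msa, tree = tree, clades = clades, fragments = fragments)
}

write_run_artifacts <- function(config, panel, manifest, hits, prs, evb,
                                labels, summaries, phylo) {
  out <- config$out_dir
  paths <- list()
  paths$hits <- file.path(out, "hits_forward.tsv")
  hh <- hits
  if (nrow(hh)) {
    export <- data.frame(dataset_id = hh$dataset_id, qseqid = hh$query_id,
                         sseqid = hh$target_id,
                         pident = round(100 * hh$identity, 2),
                         length = hh$aligned_columns,
                         evalue = fmt_num(hh$evalue),
                         bitscore = round(hh$bitscore, 1), frame = hh$frame,
                         qstart = hh$q_beg + 1L, qend = hh$q_end,
                         sstart = hh$t_beg + 1L, send = hh$t_end,
                         stringsAsFactors = FALSE)
  } else {
    export <- data.frame(dataset_id = character(), qseqid = character(),
                         sseqid = character(), pident = numeric(),
                         length = integer(), evalue = character(),
                         bitscore = numeric(), frame = character(),
                         qstart = integer(), qend = integer(),
                         sstart = integer(), send = integer(),
                         stringsAsFactors = FALSE)
  }
  write_table(export, names(export), paths$hits)

  paths$prs <- file.path(out, "prs_report.tsv")
  pr <- prs
  pr$host_phylum <- vapply(strsplit(pr$host_lineage, ";", fixed = TRUE),
                           function(x) if (length(x) >= 2) x[2] else "", "")
  pr$locus <- sprintf("%d-%d", pr$t_beg + 1L, pr$t_end)
  schema <- c("prs_id", "dataset_id", "host_phylum", "target_id", "locus",
              "gene_class", "fwd_evalue", "recip_evalue",
              "best_reference_identity", "ref_genus")
  if (!nrow(pr)) {
    pr <- as.data.frame(setNames(rep(list(character()), length(schema)),
                                 schema), stringsAsFactors = FALSE)
  }
  write_table(pr, schema, paths$prs)

  paths$evidence <- file.path(out, "evidence.tsv")
  write_table(evb$evidence, names(evb$evidence), paths$evidence)
  paths$matches_bed <- file.path(out, "genomic_matches.bed")
  write_matches_bed(evb$matches, paths$matches_bed)
  paths$labels <- file.path(out, "labels.tsv")
  write_table(labels, names(labels), paths$labels)
  paths$summary_by_phylum <- file.path(out, "summary_by_phylum.tsv")
  write_table(summaries$by_phylum, names(summaries$by_phylum),
              paths$summary_by_phylum)
  paths$summary_by_origin <- file.path(out, "summary_by_origin.tsv")
  write_table(summaries$by_origin, names(summaries$by_origin),
              paths$summary_by_origin)
  paths$summary_by_bin <- file.path(out, "summary_by_bin.tsv")
  write_table(summaries$by_bin, names(summaries$by_bin),
              paths$summary_by_bin)
  paths$discarded <- file.path(out, "discarded.tsv")
  write_table(summaries$discarded, names(summaries$discarded),
              paths$discarded)
  if (!is.null(phylo)) {
    paths$alignment_fasta <- file.path(out, "sf3_alignment.fasta")
    write_msa_fasta(phylo$msa, paths$alignment_fasta)
    paths$alignment_phylip <- file.path(out, "sf3_alignment.phy")
    write_msa_phylip(phylo$msa, paths$alignment_phylip)
    paths$tree <- file.path(out, "sf3_tree.nwk")
    ape::write.tree(phylo$tree, file = paths$tree)
    paths$clades <- file.path(out, "clade_report.tsv")
    write_table(phylo$clades, names(phylo$clades), paths$clades)
  }
  paths$manifest_json <- file.path(out, "run_manifest.json")
  write_run_manifest(config, paths$manifest_json)
  paths
}

# Versioned run manifest: echoed config (thresholds and overrides), input
# checksums and the seed; no timestamps, so reruns are byte-identical.
write_run_manifest <- function(config, path) {
  inputs <- c(panel_fasta = config$panel_fasta,
              panel_annotations = config$panel_annotations,
              manifest = config$manifest, decoys_fasta = config$decoys_fasta,
              te_library_fasta = config$te_library_fasta,
              sf3_refs_fasta = config$sf3_refs_fasta)
  sums <- vapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    "")
  cfg <- unclass(config)
  cfg$out_dir <- NULL # path-independent manifests
  for (f in names(inputs)) cfg[[f]] <- basename(cfg[[f]] %||% "")
  obj <- list(tool = "parvoscreen",
              version = as.character(utils::packageVersion("parvoscreen")),
              config = cfg, input_md5 = as.list(sums))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
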