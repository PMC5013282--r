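# Synthetic planted-truth benchmark generator: mock viral panel, host
# transcriptomes/genomes with planted extant, integrated-intact,
# integrated-degraded and contaminant events, plus the truth table the
# acceptance checks score against.

AA_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
             Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
             L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
             S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

default_hosts <- function() {
  data.frame(
    host_id = c("ant", "mosq", "shrimp", "mouse", "frog", "fluke", "snail",
                "plant"),
    lineage = c("Metazoa;Arthropoda;Insecta;Formicid_sp",
                "Metazoa;Arthropoda;Insecta;Culicid_sp",
                "Metazoa;Arthropoda;Malacostraca;Penaeid_sp",
                "Metazoa;Chordata;Mammalia;Murid_sp",
                "Metazoa;Chordata;Amphibia;Pipid_sp",
                "Metazoa;Platyhelminthes;Trematoda;Schistosomatid_sp",
                "Metazoa;Mollusca;Gastropoda;Planorbid_sp",
                "Viridiplantae;Streptophyta;Magnoliopsida;Brassicacea_sp"),
    stringsAsFactors = FALSE)
}

genus_lineage_pool <- function() {
  c("Metazoa;Arthropoda;Insecta", "Metazoa;Arthropoda;Insecta",
    "Metazoa;Arthropoda;Malacostraca", "Metazoa;Chordata;Mammalia",
    "Metazoa;Platyhelminthes;Trematoda", "Metazoa;Mollusca;Gastropoda")
}

#' Generator configuration
#'
#' Defaults define the package's standard benchmark: a genus-structured
#' 6-genus / 3-species panel with an SF3-like conserved core in every NS,
#' eight hosts spanning six phyla (transcriptome + genome each), and a
#' planted event mix of extant transcripts, intact and degraded
#' integrations, cross-host contaminants and decoy-derived fragments.
#' Divergences are realised by codon-level substitution with transition
#' bias, so nucleotide and amino-acid identity decouple.
#'
#' @param seed mandatory integer seed.
#' @param ... overrides for any default field.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genera = 6L, species_per_genus = 3L,
    ns_len = 500L, vp_len = 550L, sf3_offset = 150L, sf3_len = 191L,
    intra_div = 0.08, inter_div = 0.40, core_scale = 0.5,
    outgroup_div = 0.55,
    gc = 0.42,
    transcripts_per_host = 50L, transcript_len = c(400L, 1500L),
    contigs_per_host = 2L, contig_len = 30000L,
    n_extant = 10L, n_intact = 4L, n_degraded = 6L, n_contaminant = 4L,
    n_decoy = 5L,
    extant_div = c(0.20, 0.45), integrated_div = 0.18,
    contaminant_div = 0.04, copy_div_nt = 0.01,
    stop_rate = 0.02, degraded_indel_prob = 0.5,
    degraded_expressed_prob = 0.5,
    te_n = 5L, te_len = 800L, te_flank_prob = 0.6, te_div = 0.02,
    kappa = 4)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown generator field: ", bad[1])
  cfg[names(over)] <- over
  rates <- c(cfg$intra_div, cfg$inter_div, cfg$integrated_div,
             cfg$contaminant_div, cfg$copy_div_nt, cfg$stop_rate,
             cfg$te_flank_prob, cfg$gc)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  structure(cfg, class = "generator_config")
}

random_nt <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n, start_met = FALSE) {
  body <- sample(names(AA_FREQ), n - as.integer(start_met), replace = TRUE,
                 prob = AA_FREQ)
  paste0(if (start_met) "M" else "", paste(body, collapse = ""))
}

# substitute residues at per-site probability `rate` (optionally a reduced
# rate inside `core`, a c(beg, end) 1-based inclusive interval)
mutate_protein <- function(aa, rate, core = NULL, core_rate = rate,
                           keep_start = FALSE) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  r <- rep(rate, length(ch))
  if (!is.null(core)) r[core[1]:core[2]] <- core_rate
  if (keep_start) r[1] <- 0
  hit <- runif(length(ch)) < r
  for (i in which(hit)) {
    repeat {
      new <- sample(names(AA_FREQ), 1, prob = AA_FREQ)
      if (new != ch[i]) break
    }
    ch[i] <- new
  }
  paste(ch, collapse = "")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# reverse-translate a protein, sampling codons uniformly per residue; a
# terminal stop codon is appended
reverse_translate <- function(aa, add_stop = TRUE) {
  tab <- codon_table()
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  cods <- vapply(ch, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, "")
  if (add_stop) cods <- c(cods, sample(c("TAA", "TAG", "TGA"), 1))
  paste(cods, collapse = "")
}

translate_cds <- function(nt) translate_nt(nt)

# Codon-level substitution with transition bias kappa; stop-creating (and,
# if the source codon is a stop, stop-destroying) mutations are reverted
# when forbid_stops is TRUE.
mutate_codons <- function(nt, rate, kappa = 4, forbid_stops = TRUE) {
  if (rate <= 0) return(nt)
  ch <- strsplit(nt, "", fixed = TRUE)[[1]]
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  others <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  hit <- which(runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T"))
  old <- ch
  for (i in hit) {
    if (runif(1) < kappa / (kappa + 2)) ch[i] <- transitions[[ch[i]]]
    else ch[i] <- sample(others[[ch[i]]], 1)
  }
  if (forbid_stops) {
    nc <- length(ch) %/% 3
    stops <- c("TAA", "TAG", "TGA")
    for (k in seq_len(nc)) {
      idx <- (3 * (k - 1) + 1):(3 * k)
      cod <- paste(ch[idx], collapse = "")
      cod_old <- paste(old[idx], collapse = "")
      if ((cod %in% stops) != (cod_old %in% stops)) ch[idx] <- old[idx]
    }
  }
  paste(ch, collapse = "")
}

# positional amino-acid divergence between two equal-length CDS translations
aa_divergence <- function(cds_a, cds_b) {
  a <- strsplit(translate_cds(cds_a), "", fixed = TRUE)[[1]]
  b <- strsplit(translate_cds(cds_b), "", fixed = TRUE)[[1]]
  n <- min(length(a), length(b))
  mean(a[seq_len(n)] != b[seq_len(n)])
}

# replace codons by stop codons at per-codon probability stop_rate (interior
# codons only); if none lands, one is forced at the middle codon (the
# documented deterministic re-draw rule). Returns list(nt, n_stops).
plant_stops <- function(nt, stop_rate) {
  ch <- strsplit(nt, "", fixed = TRUE)[[1]]
  nc <- length(ch) %/% 3
  cand <- seq(6, nc - 6)
  hit <- cand[runif(length(cand)) < stop_rate]
  if (!length(hit)) hit <- cand[ceiling(length(cand) / 2)]
  for (k in hit) {
    idx <- (3 * (k - 1) + 1):(3 * k)
    ch[idx] <- strsplit(sample(c("TAA", "TAG", "TGA"), 1), "")[[1]]
  }
  list(nt = paste(ch, collapse = ""), n_stops = length(hit))
}

delete_one_nt <- function(nt) {
  pos <- sample.int(nchar(nt) - 40, 1) + 20
  paste0(substr(nt, 1, pos - 1), substr(nt, pos + 1, nchar(nt)))
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Generate the synthetic reference panel
#'
#' Builds a genus-structured panel: one ancestral NS (carrying a conserved
#' SF3-like core) and VP, per-genus ancestors at the inter-genus divergence
#' (core mutating at `core_scale` times the rate), species within each genus
#' at the intra-genus divergence, plus one strongly diverged outgroup
#' protein standing in for the poxvirus D5 helicase. Deterministic under
#' the config seed.
#'
#' @param cfg a [generator_config()].
#' @return list with `panel` (a reference panel), `cds` (named CDS vector,
#'   one per panel protein), `sf3_refs` (AA [seq_set()] of reference SF3
#'   fragments incl. the outgroup's), and `decoys` /`decoy_cds` (decoy
#'   protein set for reciprocal searches and the plantable decoy CDSs).
#' @export
generate_panel <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    core <- c(cfg$sf3_offset + 1L, cfg$sf3_offset + cfg$sf3_len)
    # viral ORFs begin with a start codon: roots are anchored on Met and the
    # start survives mutation (restore_start in the planting helpers)
    root_ns <- random_protein(cfg$ns_len, start_met = TRUE)
    root_vp <- random_protein(cfg$vp_len, start_met = TRUE)
    pool <- rep_len(genus_lineage_pool(), cfg$n_genera)
    ids <- character(); seqs <- character(); genes <- character()
    genera <- character(); lineages <- character(); outg <- logical()
    for (g in seq_len(cfg$n_genera)) {
      gname <- sprintf("genus%02d", g)
      g_ns <- mutate_protein(root_ns, cfg$inter_div, core,
                             cfg$inter_div * cfg$core_scale, keep_start = TRUE)
      g_vp <- mutate_protein(root_vp, cfg$inter_div, keep_start = TRUE)
      for (s in seq_len(cfg$species_per_genus)) {
        ns <- mutate_protein(g_ns, cfg$intra_div, core,
                             cfg$intra_div * cfg$core_scale, keep_start = TRUE)
        vp <- mutate_protein(g_vp, cfg$intra_div, keep_start = TRUE)
        ids <- c(ids, sprintf("%s_sp%d_NS", gname, s),
                 sprintf("%s_sp%d_VP", gname, s))
        seqs <- c(seqs, ns, vp)
        genes <- c(genes, "NS", "VP")
        genera <- c(genera, gname, gname)
        lineages <- c(lineages, pool[g], pool[g])
        outg <- c(outg, FALSE, FALSE)
      }
    }
    og <- mutate_protein(root_ns, cfg$outgroup_div, core,
                         cfg$outgroup_div * 0.8)
    ids <- c(ids, "outgroupD5")
    seqs <- c(seqs, og)
    genes <- c(genes, "OTHER")
    genera <- c(genera, "")
    lineages <- c(lineages, "")
    outg <- c(outg, TRUE)
    prot <- seq_set(ids, seqs, moltype = "AA")
    ann <- data.frame(id = ids, gene = genes, genus = genera,
                      host_lineage = lineages, is_outgroup = outg,
                      stringsAsFactors = FALSE)
    panel <- make_reference_panel(prot, ann)
    cds <- setNames(vapply(seqs, reverse_translate, ""), ids)
    is_ns <- genes == "NS" | outg
    sf3_refs <- seq_set(paste0(ids[is_ns], "_sf3"),
                        substr(seqs[is_ns], core[1], core[2]),
                        moltype = "AA")
    # decoys: a distantly related non-panel protein family, shuffled panel
    # entries and unrelated random proteins
    decoy_root <- mutate_protein(root_ns, 0.5)
    fam <- vapply(seq_len(3), function(i)
      mutate_protein(decoy_root, 0.08), "")
    shuf <- vapply(seqs[seq_len(min(5, length(seqs)))], shuffle_seq, "")
    rand <- vapply(seq_len(3), function(i)
      random_protein(cfg$ns_len), "")
    decoys <- seq_set(
      c(sprintf("decoyfam%d", seq_along(fam)),
        sprintf("decoyshuf%d", seq_along(shuf)),
        sprintf("decoyrand%d", seq_along(rand))),
      c(fam, unname(shuf), rand), moltype = "AA")
    decoy_cds <- setNames(vapply(fam, reverse_translate, ""),
                          sprintf("decoyfam%d", seq_along(fam)))
    list(panel = panel, cds = cds, sf3_refs = sf3_refs, decoys = decoys,
         decoy_cds = decoy_cds)
  })
}

first_compatible_genus <- function(panel, host_lineage, want_compatible) {
  ann <- panel$annotations[!panel$annotations$is_outgroup, ]
  gen <- unique(ann[, c("genus", "host_lineage")])
  ok <- vapply(gen$host_lineage, function(vl) {
    isTRUE(lineage_compatible(vl, host_lineage) == want_compatible)
  }, TRUE)
  if (any(ok)) gen$genus[ok] else gen$genus
}

#' Generate host datasets with planted events and the truth table
#'
#' Background transcripts and genome contigs are order-0 GC-controlled
#' random sequence. Event types: EXTANT plants a diverged viral CDS into a
#' transcript only; INTEGRATED_INTACT plants an intact NS+VP cassette into
#' the genome and a >=99%-identical copy into a transcript;
#' INTEGRATED_DEGRADED plants a genome copy carrying premature stop codons
#' (rejection-sampled to at least one), optionally a single-nucleotide
#' deletion and TE insertions inside the 500-nt flanks, plus an expressed
#' transcript copy with probability `degraded_expressed_prob`; CONTAMINANT
#' plants a near-identical copy of a panel virus whose known host lineage is
#' incompatible with the dataset's host; DECOY plants fragments of the
#' decoy protein family (no PRS expected). Realized divergences and planted
#' features are recorded per placed copy in the truth table.
#'
#' @param cfg a [generator_config()].
#' @param pan output of [generate_panel()].
#' @return a `synthetic_benchmark`: list with `datasets` (named list of NT
#'   [seq_set()]s), `manifest`, `truth`, `te_library`, plus the panel
#'   components carried through.
#' @export
generate_host_datasets <- function(cfg, pan) {
  with_seed(derive_seed(cfg$seed, 2L), {
    hosts <- default_hosts()
    panel <- pan$panel
    ann <- panel$annotations
    datasets <- list()
    manifest <- list()
    # backgrounds
    tx <- list(); gn <- list(); tx_used <- list(); gn_slots <- list()
    for (h in seq_len(nrow(hosts))) {
      hid <- hosts$host_id[h]
      lens <- sample(seq(cfg$transcript_len[1], cfg$transcript_len[2]),
                     cfg$transcripts_per_host, replace = TRUE)
      tx[[hid]] <- vapply(lens, random_nt, "", gc = cfg$gc)
      names(tx[[hid]]) <- sprintf("%s_tr%04d", hid,
                                  seq_len(cfg$transcripts_per_host))
      tx_used[[hid]] <- logical(cfg$transcripts_per_host)
      gn[[hid]] <- vapply(rep(cfg$contig_len, cfg$contigs_per_host),
                          random_nt, "", gc = cfg$gc)
      names(gn[[hid]]) <- sprintf("%s_ctg%d", hid,
                                  seq_len(cfg$contigs_per_host))
      gn_slots[[hid]] <- vector("list", cfg$contigs_per_host)
    }
    te_library <- seq_set(sprintf("te%d", seq_len(cfg$te_n)),
                          vapply(rep(cfg$te_len, cfg$te_n), random_nt, "",
                                 gc = cfg$gc), moltype = "NT")
    truth <- list()
    eid <- 0L
    ns_ids <- ann$id[ann$gene == "NS" & !ann$is_outgroup]
    vp_ids <- ann$id[ann$gene == "VP" & !ann$is_outgroup]
    viral_hosts <- hosts$host_id[!grepl("^Viridiplantae", hosts$lineage)]

    pick_transcript <- function(hid, min_len = 0) {
      free <- which(!tx_used[[hid]] & nchar(tx[[hid]]) >= min_len)
      if (!length(free)) free <- which(!tx_used[[hid]])
      i <- free[sample.int(length(free), 1)]
      tx_used[[hid]][i] <<- TRUE
      i
    }
    plant_in_transcript <- function(hid, insert_nt) {
      i <- pick_transcript(hid)
      utr5 <- random_nt(sample(50:200, 1), cfg$gc)
      utr3 <- random_nt(sample(50:200, 1), cfg$gc)
      tx[[hid]][i] <<- paste0(utr5, insert_nt, utr3)
      list(target_id = names(tx[[hid]])[i], beg = nchar(utr5),
           end = nchar(utr5) + nchar(insert_nt))
    }
    plant_in_genome <- function(hid, insert_nt, core_offset, core_len) {
      # core_offset/core_len: the element interval inside insert_nt
      for (attempt in seq_len(60)) {
        ci <- sample.int(cfg$contigs_per_host, 1)
        L <- nchar(gn[[hid]][ci])
        lo <- 2000L
        hi <- L - 2000L - nchar(insert_nt)
        if (hi <= lo) next
        pos <- sample(lo:hi, 1)
        iv <- c(pos, pos + nchar(insert_nt))
        clash <- any(vapply(gn_slots[[hid]][[ci]], function(s)
          iv[1] < s[2] + 1500 && s[1] - 1500 < iv[2], TRUE))
        if (isTRUE(clash)) next
        gn_slots[[hid]][[ci]] <<- c(gn_slots[[hid]][[ci]], list(iv))
        s <- gn[[hid]][ci]
        gn[[hid]][ci] <<- paste0(substr(s, 1, pos),
                                 insert_nt,
                                 substr(s, pos + nchar(insert_nt) + 1, L))
        return(list(target_id = names(gn[[hid]])[ci],
                    beg = pos + core_offset,
                    end = pos + core_offset + core_len))
      }
      stop("could not place genomic insert for host ", hid)
    }
    add_truth <- function(...) {
      truth[[length(truth) + 1]] <<- data.frame(..., stringsAsFactors = FALSE)
    }

    # --- EXTANT -----------------------------------------------------------
    div_cycle <- seq(cfg$extant_div[1], cfg$extant_div[2], length.out = 4)
    for (k in seq_len(cfg$n_extant)) {
      hid <- viral_hosts[(k - 1) %% length(viral_hosts) + 1]
      hlin <- hosts$lineage[hosts$host_id == hid]
      gene_ids <- if (k %% 3 == 0) vp_ids else ns_ids
      genera_ok <- first_compatible_genus(panel, hlin, TRUE)
      cand <- gene_ids[ann$genus[match(gene_ids, ann$id)] %in% genera_ok]
      if (!length(cand)) cand <- gene_ids
      src <- cand[(k - 1) %% length(cand) + 1]
      d <- div_cycle[(k - 1) %% length(div_cycle) + 1]
      rate <- 1 - (1 - d)^(1 / 2.3) # nt rate targeting aa divergence d
      cds <- mutate_codons(pan$cds[[src]], rate, cfg$kappa, TRUE)
      realized <- aa_divergence(cds, pan$cds[[src]])
      loc <- plant_in_transcript(hid, cds)
      eid <- eid + 1L
      add_truth(event_id = sprintf("ev%03d", eid), event_type = "EXTANT",
                dataset_id = paste0(hid, "_tx"), target_id = loc$target_id,
                beg = loc$beg, end = loc$end,
                source_ref_id = src,
                source_genus = ann$genus[ann$id == src],
                realized_aa_divergence = realized, n_planted_stops = 0L,
                frameshift_planted = FALSE, te_planted_5 = FALSE,
                te_planted_3 = FALSE)
    }

    # --- INTEGRATED_INTACT ------------------------------------------------
    for (k in seq_len(cfg$n_intact)) {
      hid <- viral_hosts[(k + 1) %% length(viral_hosts) + 1]
      sp <- ns_ids[(k - 1) %% length(ns_ids) + 1]
      vp <- sub("_NS$", "_VP", sp)
      rate <- 1 - (1 - cfg$integrated_div)^(1 / 2.3)
      restore_start <- function(x) paste0("ATG", substr(x, 4, nchar(x)))
      ns_cds <- restore_start(mutate_codons(pan$cds[[sp]], rate, cfg$kappa, TRUE))
      vp_cds <- restore_start(mutate_codons(pan$cds[[vp]], rate, cfg$kappa, TRUE))
      realized <- aa_divergence(ns_cds, pan$cds[[sp]])
      spacer <- random_nt(150, cfg$gc)
      cassette <- paste0(ns_cds, spacer, vp_cds)
      gl <- plant_in_genome(hid, cassette, 0L, nchar(cassette))
      tx_copy <- mutate_codons(cassette, cfg$copy_div_nt, cfg$kappa, TRUE)
      tl <- plant_in_transcript(hid, tx_copy)
      eid <- eid + 1L
      for (copy in list(list(ds = paste0(hid, "_gn"), loc = gl),
                        list(ds = paste0(hid, "_tx"), loc = tl))) {
        add_truth(event_id = sprintf("ev%03d", eid),
                  event_type = "INTEGRATED_INTACT", dataset_id = copy$ds,
                  target_id = copy$loc$target_id, beg = copy$loc$beg,
                  end = copy$loc$end, source_ref_id = sp,
                  source_genus = ann$genus[ann$id == sp],
                  realized_aa_divergence = realized, n_planted_stops = 0L,
                  frameshift_planted = FALSE, te_planted_5 = FALSE,
                  te_planted_3 = FALSE)
      }
    }

    # --- INTEGRATED_DEGRADED ---------------------------------------------
    for (k in seq_len(cfg$n_degraded)) {
      hid <- viral_hosts[(k + 3) %% length(viral_hosts) + 1]
      src <- ns_ids[(k + 2) %% length(ns_ids) + 1]
      rate <- 1 - (1 - cfg$integrated_div)^(1 / 2.3)
      base <- mutate_codons(pan$cds[[src]], rate, cfg$kappa, TRUE)
      realized <- aa_divergence(base, pan$cds[[src]])
      st <- plant_stops(base, cfg$stop_rate)
      element <- st$nt
      fs <- runif(1) < cfg$degraded_indel_prob
      if (fs) element <- delete_one_nt(element)
      te5 <- runif(1) < cfg$te_flank_prob
      te3 <- runif(1) < cfg$te_flank_prob
      gap5 <- random_nt(sample(40:250, 1), cfg$gc)
      gap3 <- random_nt(sample(40:250, 1), cfg$gc)
      left <- if (te5) paste0(mutate_codons(te_library$seq[
        (k - 1) %% cfg$te_n + 1], cfg$te_div, cfg$kappa, FALSE), gap5)
      else gap5
      right <- if (te3) paste0(gap3, mutate_codons(te_library$seq[
        k %% cfg$te_n + 1], cfg$te_div, cfg$kappa, FALSE))
      else gap3
      insert <- paste0(left, element, right)
      gl <- plant_in_genome(hid, insert, nchar(left), nchar(element))
      eid <- eid + 1L
      add_truth(event_id = sprintf("ev%03d", eid),
                event_type = "INTEGRATED_DEGRADED",
                dataset_id = paste0(hid, "_gn"), target_id = gl$target_id,
                beg = gl$beg, end = gl$end, source_ref_id = src,
                source_genus = ann$genus[ann$id == src],
                realized_aa_divergence = realized,
                n_planted_stops = st$n_stops, frameshift_planted = fs,
                te_planted_5 = te5, te_planted_3 = te3)
      if (runif(1) < cfg$degraded_expressed_prob) {
        tx_copy <- mutate_codons(element, cfg$copy_div_nt, cfg$kappa, FALSE)
        tl <- plant_in_transcript(hid, tx_copy)
        add_truth(event_id = sprintf("ev%03d", eid),
                  event_type = "INTEGRATED_DEGRADED",
                  dataset_id = paste0(hid, "_tx"), target_id = tl$target_id,
                  beg = tl$beg, end = tl$end, source_ref_id = src,
                  source_genus = ann$genus[ann$id == src],
                  realized_aa_divergence = realized,
                  n_planted_stops = st$n_stops, frameshift_planted = fs,
                  te_planted_5 = te5, te_planted_3 = te3)
      }
    }

    # --- CONTAMINANT ------------------------------------------------------
    cont_hosts <- intersect(c("frog", "plant", "ant", "snail"),
                            hosts$host_id)
    for (k in seq_len(cfg$n_contaminant)) {
      hid <- cont_hosts[(k - 1) %% length(cont_hosts) + 1]
      hlin <- hosts$lineage[hosts$host_id == hid]
      genera_bad <- first_compatible_genus(panel, hlin, FALSE)
      cand <- ns_ids[ann$genus[match(ns_ids, ann$id)] %in% genera_bad]
      src <- cand[(k - 1) %% length(cand) + 1]
      rate <- 1 - (1 - cfg$contaminant_div)^(1 / 2.3)
      cds <- mutate_codons(pan$cds[[src]], rate, cfg$kappa, TRUE)
      realized <- aa_divergence(cds, pan$cds[[src]])
      loc <- plant_in_transcript(hid, cds)
      eid <- eid + 1L
      add_truth(event_id = sprintf("ev%03d", eid), event_type = "CONTAMINANT",
                dataset_id = paste0(hid, "_tx"), target_id = loc$target_id,
                beg = loc$beg, end = loc$end, source_ref_id = src,
                source_genus = ann$genus[ann$id == src],
                realized_aa_divergence = realized, n_planted_stops = 0L,
                frameshift_planted = FALSE, te_planted_5 = FALSE,
                te_planted_3 = FALSE)
    }

    # --- DECOY plants (no PRS expected) ----------------------------------
    for (k in seq_len(cfg$n_decoy)) {
      hid <- viral_hosts[(k + 2) %% length(viral_hosts) + 1]
      di <- (k - 1) %% length(pan$decoy_cds) + 1
      cds <- mutate_codons(pan$decoy_cds[[di]], 0.02, cfg$kappa, TRUE)
      loc <- plant_in_transcript(hid, cds)
      eid <- eid + 1L
      add_truth(event_id = sprintf("ev%03d", eid), event_type = "DECOY",
                dataset_id = paste0(hid, "_tx"), target_id = loc$target_id,
                beg = loc$beg, end = loc$end,
                source_ref_id = names(pan$decoy_cds)[di], source_genus = "",
                realized_aa_divergence = 0.5, n_planted_stops = 0L,
                frameshift_planted = FALSE, te_planted_5 = FALSE,
                te_planted_3 = FALSE)
    }

    for (h in seq_len(nrow(hosts))) {
      hid <- hosts$host_id[h]
      datasets[[paste0(hid, "_tx")]] <-
        seq_set(names(tx[[hid]]), unname(tx[[hid]]), moltype = "NT")
      datasets[[paste0(hid, "_gn")]] <-
        seq_set(names(gn[[hid]]), unname(gn[[hid]]), moltype = "NT")
      manifest[[length(manifest) + 1]] <- data.frame(
        dataset_id = c(paste0(hid, "_tx"), paste0(hid, "_gn")),
        kind = c("TRANSCRIPTOME", "GENOME"),
        host_lineage = hosts$lineage[h],
        path = c(paste0(hid, "_tx.fasta"), paste0(hid, "_gn.fasta")),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- expected_labels(truth, pan)
    structure(list(datasets = datasets,
                   manifest = do.call(rbind, manifest), truth = truth,
                   te_library = te_library, panel = panel, cds = pan$cds,
                   sf3_refs = pan$sf3_refs, decoys = pan$decoys,
                   hosts = hosts, config = cfg),
              class = "synthetic_benchmark")
  })
}

#' Expected classifier output for each truth row
#'
#' Derives, from the realized (not target) event parameters, the identity
#' bin, origin and contaminant flag the classifier should emit under its
#' documented rules.
#'
#' @param truth truth table (one row per planted copy).
#' @param pan panel bundle ([generate_panel()]); used for host-lineage
#'   incompatibility of contaminant sources.
#' @return the truth table with `expected_identity_bin`, `expected_origin`
#'   and `expected_contaminant` columns (re)computed.
#' @export
expected_labels <- function(truth, pan) {
  ann <- pan$panel$annotations
  hosts <- default_hosts()
  ident <- 1 - truth$realized_aa_divergence
  truth$expected_identity_bin <- ifelse(truth$event_type == "DECOY", "NONE",
                                        identity_bin(pmax(0, pmin(1, ident))))
  truth$expected_origin <- c(
    EXTANT = "EXTANT_CANDIDATE", INTEGRATED_INTACT = "ENDOGENOUS_INTACT",
    INTEGRATED_DEGRADED = "ENDOGENOUS_DEGRADED",
    CONTAMINANT = "EXTANT_CANDIDATE", DECOY = "NONE")[truth$event_type]
  host_of <- sub("_(tx|gn)$", "", truth$dataset_id)
  hlin <- hosts$lineage[match(host_of, hosts$host_id)]
  vlin <- ann$host_lineage[match(truth$source_ref_id, ann$id)]
  incompat <- vapply(seq_len(nrow(truth)), function(i) {
    cmp <- lineage_compatible(vlin[i], hlin[i])
    isTRUE(!cmp)
  }, TRUE)
  truth$expected_contaminant <- truth$event_type == "CONTAMINANT" &
    truth$expected_identity_bin == "KNOWN_VIRUS_LIKE" & incompat
  rownames(truth) <- NULL
  truth
}

#' Write a synthetic benchmark to disk
#'
#' Writes every dataset FASTA, the dataset manifest, panel FASTA +
#' annotation TSV, SF3 reference fragments, decoys, TE library, the truth
#' table and a BED of planted genomic intervals.
#'
#' @param bench a `synthetic_benchmark`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the paths written.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ds in names(bench$datasets)) {
    paths[[ds]] <- file.path(dir, paste0(ds, ".fasta"))
    write_fasta(bench$datasets[[ds]], paths[[ds]])
  }
  paths$manifest <- file.path(dir, "manifest.tsv")
  write_table(bench$manifest, names(bench$manifest), paths$manifest)
  paths$panel <- file.path(dir, "panel.fasta")
  write_fasta(bench$panel$proteins, paths$panel)
  paths$panel_annotations <- file.path(dir, "panel_annotations.tsv")
  write_table(bench$panel$annotations, names(bench$panel$annotations),
              paths$panel_annotations)
  paths$sf3_refs <- file.path(dir, "sf3_refs.fasta")
  write_fasta(bench$sf3_refs, paths$sf3_refs)
  paths$decoys <- file.path(dir, "decoys.fasta")
  write_fasta(bench$decoys, paths$decoys)
  paths$te_library <- file.path(dir, "te_library.fasta")
  write_fasta(bench$te_library, paths$te_library)
  paths$truth <- file.path(dir, "truth_table.tsv")
  write_table(bench$truth, names(bench$truth), paths$truth)
  gentries <- bench$truth[grepl("_gn$", bench$truth$dataset_id), ,
                          drop = FALSE]
  paths$planted_bed <- file.path(dir, "planted.bed")
  con <- file(paths$planted_bed, open = "wb")
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t+", gentries$target_id,
                     gentries$beg, gentries$end, gentries$event_id), con)
  close(con)
  invisible(paths)
}

#' Score pipeline output against a truth table
#'
#' A truth row is recovered when a confirmed PRS in the same dataset and
#' target overlaps its planted interval; a PRS is a true positive when it
#' overlaps any non-DECOY truth row. Origin classification is scored per
#' recovered truth row against the expected origin (macro-averaged F1 over
#' the expected origin classes, missed rows counting as errors), and the
#' contaminant flag rate is the fraction of expected contaminants whose
#' matched PRS was flagged.
#'
#' @param prs_table confirmed PRS table.
#' @param labels labels table ([classify_prs()]).
#' @param truth truth table.
#' @return list with `precision`, `recall`, `origin_macro_f1`,
#'   `contaminant_flagged`, and the per-row `detail` table.
#' @export
score_against_truth <- function(prs_table, labels, truth) {
  viral <- truth[truth$event_type != "DECOY", , drop = FALSE]
  lab <- merge(prs_table, labels, by = "prs_id")
  match_of <- rep(NA_character_, nrow(viral))
  pred_origin <- rep("MISSED", nrow(viral))
  pred_cont <- rep(FALSE, nrow(viral))
  for (i in seq_len(nrow(viral))) {
    cand <- lab[lab$dataset_id == viral$dataset_id[i] &
                  lab$target_id == viral$target_id[i] &
                  lab$t_beg < viral$end[i] & viral$beg[i] < lab$t_end, ,
                drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$t_end, viral$end[i]) - pmax(cand$t_beg, viral$beg[i])
    j <- which.max(ov)
    match_of[i] <- cand$prs_id[j]
    pred_origin[i] <- cand$origin[j]
    pred_cont[i] <- isTRUE(cand$contaminant_suspect[j])
  }
  recall <- mean(!is.na(match_of))
  tp_prs <- vapply(seq_len(nrow(prs_table)), function(p) {
    any(viral$dataset_id == prs_table$dataset_id[p] &
          viral$target_id == prs_table$target_id[p] &
          viral$beg < prs_table$t_end[p] & prs_table$t_beg[p] < viral$end)
  }, TRUE)
  precision <- if (nrow(prs_table)) mean(tp_prs) else NA_real_
  classes <- sort(unique(viral$expected_origin))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(viral$expected_origin == cl & pred_origin == cl)
    fp <- sum(viral$expected_origin != cl & pred_origin == cl)
    fn <- sum(viral$expected_origin == cl & pred_origin != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0)
  is_cont <- viral$expected_contaminant
  cont_rate <- if (any(is_cont)) mean(pred_cont[is_cont]) else NA_real_
  detail <- cbind(viral[, c("event_id", "event_type", "dataset_id",
                            "target_id", "expected_origin",
                            "expected_contaminant")],
                  matched_prs = match_of, predicted_origin = pred_origin,
                  predicted_contaminant = pred_cont)
  list(precision = precision, recall = recall,
       origin_macro_f1 = mean(f1), contaminant_flagged = cont_rate,
       detail = detail)
}
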