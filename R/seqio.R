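# Sequence and table input/output: FASTA via Biostrings, TSV tables with a
# fixed dialect (tab-separated, one header row, '#' comments permitted).

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")

#' Construct a sequence set
#'
#' A `seq_set` is the package's in-memory sequence container: a data frame
#' with columns `id`, `desc` and `seq`, carrying its molecule type
#' (`"NT"` or `"AA"`) as an attribute. Residues are stored uppercase; ids
#' must be unique and whitespace-free.
#'
#' @param id character vector of record ids.
#' @param seq character vector of residues.
#' @param desc optional description strings (default empty).
#' @param moltype `"NT"` or `"AA"`.
#' @return a `seq_set` data frame.
#' @export
seq_set <- function(id, seq, desc = "", moltype = c("NT", "AA")) {
  moltype <- match.arg(moltype)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- rep_len(as.character(desc), length(id))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (any(grepl("\\s", id))) stop("sequence ids must not contain whitespace: ",
                                  id[grepl("\\s", id)][1])
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  validate_residues(seq, id, moltype)
  out <- data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  class(out) <- c("seq_set", "data.frame")
  out
}

validate_residues <- function(seq, id, moltype, allow_stop = TRUE) {
  legal <- if (moltype == "NT") NT_ALPHABET else AA_ALPHABET
  if (!allow_stop) legal <- setdiff(legal, "*")
  pat <- paste0("[^", gsub("\\*", "\\\\*", paste(legal, collapse = "")), "]")
  bad <- regexpr(pat, seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 moltype, substr(seq[i], bad[i], bad[i]), id[i], bad[i]))
  }
  invisible(TRUE)
}

seq_moltype <- function(x) attr(x, "moltype")

#' Read a FASTA file into a sequence set
#'
#' Residues are uppercased on input; the description is everything after the
#' first whitespace on the header line. Duplicate ids and residues outside
#' the declared alphabet are errors; an empty file yields an empty set.
#'
#' @param path path to a plain (uncompressed) FASTA file.
#' @param moltype `"NT"` (alphabet ACGTN) or `"AA"` (20 amino acids plus X;
#'   `*` is reserved for in-silico translation products and rejected here).
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, moltype = c("NT", "AA")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(seq_set(character(), character(), character(), moltype))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(ss))
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  validate_residues(seq, id, moltype, allow_stop = FALSE)
  out <- data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "moltype") <- moltype
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Write a sequence set to FASTA
#'
#' Output wraps residues at 60 columns. Headers are `>id desc` (description
#' omitted when empty).
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(setNames(x$seq, ifelse(nzchar(x$desc),
                                                      paste(x$id, x$desc),
                                                      x$id)))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Load a reference protein panel
#'
#' Reads the panel FASTA (amino acid) and its annotation table and checks the
#' panel invariants: at least one NS and one VP entry, at most one outgroup,
#' a non-empty genus for every non-outgroup entry, and an annotation row for
#' every sequence.
#'
#' @param fasta path to the panel protein FASTA.
#' @param annotations path to a TSV with columns `id`, `gene`
#'   (NS/VP/OTHER), `genus`, `host_lineage` (semicolon-separated, ordered
#'   kingdom to species) and `is_outgroup` (TRUE/FALSE).
#' @return a `reference_panel`: list with elements `proteins` (a
#'   [seq_set()]) and `annotations` (data frame, same order).
#' @export
load_reference_panel <- function(fasta, annotations) {
  prot <- read_fasta(fasta, "AA")
  ann <- read_tsv_table(annotations)
  need <- c("id", "gene", "genus", "host_lineage", "is_outgroup")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  ann$is_outgroup <- as.logical(ann$is_outgroup)
  unknown <- setdiff(prot$id, ann$id)
  if (length(unknown)) stop("panel protein without annotation row: ",
                            unknown[1])
  ann <- ann[match(prot$id, ann$id), , drop = FALSE]
  rownames(ann) <- NULL
  bad_gene <- setdiff(unique(ann$gene), c("NS", "VP", "OTHER"))
  if (length(bad_gene)) stop("unknown gene label: ", bad_gene[1])
  make_reference_panel(prot, ann)
}

make_reference_panel <- function(proteins, annotations) {
  ann <- annotations
  if (sum(ann$gene == "NS" & !ann$is_outgroup) < 1)
    stop("unusable panel: no NS entry")
  if (sum(ann$gene == "VP" & !ann$is_outgroup) < 1)
    stop("unusable panel: no VP entry")
  if (sum(ann$is_outgroup) > 1) stop("panel has more than one outgroup")
  if (any(!nzchar(ann$genus) & !ann$is_outgroup))
    stop("non-outgroup panel entry with empty genus: ",
         ann$id[!nzchar(ann$genus) & !ann$is_outgroup][1])
  structure(list(proteins = proteins, annotations = ann),
            class = "reference_panel")
}

panel_outgroup_id <- function(panel) {
  og <- panel$annotations$id[panel$annotations$is_outgroup]
  if (length(og)) og else NA_character_
}

#' Read a dataset manifest
#'
#' The manifest maps each dataset file to its kind and host lineage, one row
#' per dataset: columns `dataset_id`, `kind` (TRANSCRIPTOME / GENOME /
#' PROTEIN), `host_lineage` (semicolon-separated) and `path`. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest TSV path.
#' @return data frame of dataset descriptors.
#' @export
read_dataset_manifest <- function(path) {
  m <- read_tsv_table(path)
  need <- c("dataset_id", "kind", "host_lineage", "path")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(m$kind), c("TRANSCRIPTOME", "GENOME", "PROTEIN"))
  if (length(bad)) stop("unknown dataset kind: ", bad[1])
  nrank <- vapply(strsplit(m$host_lineage, ";", fixed = TRUE), length, 1L)
  if (any(nrank < 2)) stop("host_lineage needs at least 2 ranks: ",
                           m$dataset_id[nrank < 2][1])
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Write records as a TSV table
#'
#' Tab-separated with one header row and a deterministic field order; string,
#' integer and double fields round-trip losslessly through
#' [read_tsv_table()]. Rows missing a schema field are an error.
#'
#' @param records data frame (or list of named lists).
#' @param schema character vector: the output columns, in order.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, schema, path) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      miss <- setdiff(schema, names(r))
      if (length(miss)) stop("record missing field '", miss[1], "'")
      as.data.frame(r[schema], stringsAsFactors = FALSE)
    })) %||% as.data.frame(setNames(rep(list(character()), length(schema)),
                                    schema))
  }
  miss <- setdiff(schema, names(records))
  if (length(miss))
    stop("record missing field '", miss[1], "'")
  records <- records[, schema, drop = FALSE]
  for (j in seq_along(records)) {
    if (is.double(records[[j]])) # 17 significant digits: doubles round-trip
      records[[j]] <- fmt_num(records[[j]], digits = 17)
  }
  con <- file(path, open = "wb") # "wb": byte-identical output across platforms
  on.exit(close(con))
  writeLines(paste(schema, collapse = "\t"), con)
  if (nrow(records)) {
    lines <- do.call(paste, c(unname(as.list(records)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' `#`-prefixed comment lines are skipped; all columns are read as character
#' and then converted by type inspection (integers, doubles) so numeric
#' fields round-trip.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  x <- read.delim(path, sep = "\t", quote = "", comment.char = "#",
                  colClasses = "character", check.names = FALSE,
                  stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (!length(v)) next
    if (all(grepl("^-?[0-9]+$", v))) {
      x[[j]] <- as.integer(v)
    } else if (all(grepl("^(NA|[-+]?([0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?))$", v)) &&
               any(grepl("[.eE]", v))) {
      x[[j]] <- as.numeric(ifelse(v == "NA", NA, v))
    }
  }
  x
}
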