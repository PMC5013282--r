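test_that("FASTA reading normalises case and parses descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first record", "acgt", ">b", "GGGGT"), f)
  x <- read_fasta(f, "NT")
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$seq, c("ACGT", "GGGGT"))
  expect_equal(x$desc, c("first record", ""))
})

test_that("FASTA reading enforces record invariants", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f, "NT"), "duplicate.*a")
  writeLines(c(">a", "ACQT"), f)
  expect_error(read_fasta(f, "NT"), "illegal NT residue 'Q'.*position 3")
  file.create(f2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_equal(nrow(read_fasta(f2, "NT")), 0)
})

test_that("FASTA round-trip is the identity on random records", {
  withr::local_seed(11)
  for (mt in c("NT", "AA")) {
    n <- 100
    ids <- paste0("rec", seq_len(n))
    seqs <- vapply(sample(30:200, n, TRUE), function(L)
      if (mt == "NT") rand_nt(L) else rand_protein(L), "")
    desc <- ifelse(runif(n) < 0.5, "", paste("desc", seq_len(n)))
    x <- seq_set(ids, seqs, desc, moltype = mt)
    f <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(x, f)
    y <- read_fasta(f, mt)
    expect_equal(y$id, x$id)
    expect_equal(y$seq, x$seq)
    expect_equal(y$desc, x$desc)
  }
})

test_that("reference panel loading checks annotations and invariants", {
  pan <- tiny_panel()
  d <- withr::local_tempdir()
  write_fasta(pan$proteins, file.path(d, "p.fasta"))
  write_table(pan$annotations, names(pan$annotations), file.path(d, "a.tsv"))
  got <- load_reference_panel(file.path(d, "p.fasta"), file.path(d, "a.tsv"))
  expect_equal(nrow(got$proteins), 5)
  expect_equal(got$annotations$gene, pan$annotations$gene)

  # panel without NS entries is unusable
  ann2 <- pan$annotations
  ann2$gene[ann2$gene == "NS"] <- "VP"
  write_table(ann2, names(ann2), file.path(d, "a2.tsv"))
  expect_error(load_reference_panel(file.path(d, "p.fasta"),
                                    file.path(d, "a2.tsv")), "no NS")

  # a protein without an annotation row is an error
  ann3 <- pan$annotations[-2, ]
  write_table(ann3, names(ann3), file.path(d, "a3.tsv"))
  expect_error(load_reference_panel(file.path(d, "p.fasta"),
                                    file.path(d, "a3.tsv")),
               "without annotation")
})

test_that("a 74-entry panel loads with genus annotations intact", {
  withr::local_seed(3)
  n_sp <- 37 # 37 species x (NS + VP) = 74 proteins
  ids <- c(rbind(sprintf("sp%02d_NS", 1:n_sp), sprintf("sp%02d_VP", 1:n_sp)))
  seqs <- vapply(rep(c(200, 220), n_sp), rand_protein, "")
  ann <- data.frame(id = ids, gene = rep(c("NS", "VP"), n_sp),
                    genus = rep(sprintf("genus%02d", (0:(n_sp - 1)) %/% 3 + 1),
                                each = 2),
                    host_lineage = "Metazoa;Arthropoda;Insecta",
                    is_outgroup = FALSE, stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  write_fasta(seq_set(ids, seqs, moltype = "AA"), file.path(d, "p.fasta"))
  write_table(ann, names(ann), file.path(d, "a.tsv"))
  got <- load_reference_panel(file.path(d, "p.fasta"), file.path(d, "a.tsv"))
  expect_equal(nrow(got$proteins), 74)
  expect_true(all(nzchar(got$annotations$genus)))
})

test_that("TSV tables have a fixed schema and round-trip losslessly", {
  d <- withr::local_tempdir()
  f <- file.path(d, "t.tsv")
  write_table(data.frame(a = character(), b = character()), c("a", "b"), f)
  expect_equal(readLines(f), "a\tb")

  df <- data.frame(a = c("x", "y", "z"), b = 1:3, c = c(0.5, 2.25, -1e-7),
                   d = c("p", "q", "r"), stringsAsFactors = FALSE)
  write_table(df, c("a", "b", "c", "d"), f)
  expect_length(readLines(f), 4)
  back <- read_tsv_table(f)
  expect_equal(back$a, df$a)
  expect_equal(back$b, df$b)
  expect_equal(back$c, df$c)

  expect_error(write_table(df, c("a", "missing"), f), "missing")

  withr::local_seed(8)
  big <- data.frame(id = paste0("r", 1:50), val = runif(50),
                    n = sample.int(1000, 50), stringsAsFactors = FALSE)
  write_table(big, names(big), f)
  back <- read_tsv_table(f)
  expect_equal(back$val, big$val)
  expect_equal(back$n, big$n)
})
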