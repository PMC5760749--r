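test_that("CDS extraction translates both strands correctly (table 11)", {
  g <- new_genome("t1", "ATGAAATAAGG",
                  tibble::tibble(locus_tag = "g1", start = 0, end = 9, strand = "+",
                                 feature_kind = "CDS", product = "x"))
  expect_equal(g$genes$aa_seq[1], "MK")

  # minus strand: gene sequence is the reverse complement of the interval,
  # checked against an independent positional reverse-complement oracle
  set.seed(42)
  for (i in 1:5) {
    prot <- random_protein(30)
    nt <- backtranslate(prot)
    genomic <- oracle_revcomp(nt)
    seqs <- paste0("ACGTAC", genomic, "TTACGT")
    g2 <- new_genome("t2", seqs,
                     tibble::tibble(locus_tag = "g1", start = 6, end = 6 + nchar(nt),
                                    strand = "-", feature_kind = "CDS", product = "x"))
    expect_equal(g2$genes$nt_seq[1], nt)
    expect_equal(g2$genes$aa_seq[1], prot)
  }
})

test_that("GTG/TTG starts are rendered as M and stops are trimmed", {
  g <- new_genome("t", "GTGAAATAA",
                  tibble::tibble(locus_tag = "g1", start = 0, end = 9, strand = "+",
                                 feature_kind = "CDS", product = "x"))
  expect_equal(g$genes$aa_seq[1], "MK")
})

test_that("CDS length not divisible by 3 is flagged partial with a warning", {
  expect_warning(
    g <- new_genome("t", "ATGAAAATAAC",
                    tibble::tibble(locus_tag = "g1", start = 0, end = 10, strand = "+",
                                   feature_kind = "CDS", product = "x")),
    "partial")
  expect_true(g$genes$partial[1])
  expect_true(is.na(g$genes$aa_seq[1]))
  expect_equal(length(proteome(g)), 0)
})

test_that("gene intervals outside the replicon are rejected", {
  expect_error(
    new_genome("t", "ATGAAATAA",
               tibble::tibble(locus_tag = "g1", start = 3, end = 12, strand = "+",
                              feature_kind = "CDS", product = "x")),
    "outside")
})

test_that("genome summary matches an independent base tally", {
  empty_genes <- tibble::tibble(
    locus_tag = character(), start = integer(), end = integer(),
    strand = character(), feature_kind = character(), product = character())
  g <- new_genome("gc", "GGCC", empty_genes)
  s <- summarize_genome(g)
  expect_equal(s$gc_percent, 100)
  expect_equal(s$n_genes, 0L)

  set.seed(7)
  seqs <- random_dna(10000, gc = 0.42)
  g2 <- new_genome("r", seqs, empty_genes)
  tally <- oracle_base_tally(seqs)
  expect_equal(sum(tally), nchar(seqs))          # per-base tallies cover everything
  gc_oracle <- 100 * (tally[["G"]] + tally[["C"]]) / sum(tally[c("A", "C", "G", "T")])
  expect_equal(summarize_genome(g2)$gc_percent, round(gc_oracle, 1))

  # ambiguity codes excluded from numerator and denominator
  g3 <- new_genome("n", "GGCCNNNN", empty_genes)
  expect_equal(summarize_genome(g3)$gc_percent, 100)
})

test_that("summary counts derive from feature kinds and product text", {
  prots <- replicate(3, random_protein(25))
  g <- toy_genome_from_proteins(prots, id = "s")
  g$genes$product <- c("Hypothetical Protein", "DNA polymerase", "hypothetical protein fragment")
  s <- summarize_genome(g)
  expect_equal(s$n_cds, 3L)
  expect_equal(s$n_hypothetical, 2L)   # case-insensitive substring match
  expect_equal(s$n_genes, s$n_cds + s$n_trna + s$n_rrna + s$n_other_rna)
})

test_that("for every complete CDS, 3*len(aa) + 3 = len(nt)", {
  set.seed(11)
  g <- toy_genome_from_proteins(replicate(6, random_protein(sample(20:60, 1))))
  cds <- g$genes[g$genes$feature_kind == "CDS" & !g$genes$partial, ]
  expect_equal(3 * nchar(cds$aa_seq) + 3, nchar(cds$nt_seq))
})

test_that("GenBank writing and reloading round-trips coordinates, strands, sequence", {
  set.seed(5)
  sim <- simulate_pair(small_sim_config(seed = 5, n_backbone = 12, regions = list()))
  g <- sim$a
  # add an rRNA and an origin-spanning CDS to exercise the full location grammar
  g$genes <- NULL
  genes <- sim$a$genes |>
    dplyr::select(locus_tag, start, end, strand, feature_kind, product)
  genes$feature_kind[3] <- "rRNA"
  genes$product[3] <- "16S ribosomal RNA"
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genome(new_genome("roundtrip", sim$a$sequence, genes),
               format = "genbank", path = path)
  back <- load_genome(path, format = "genbank")
  orig <- new_genome("roundtrip", sim$a$sequence, genes)
  expect_equal(back$sequence, orig$sequence)
  expect_equal(back$genes$start, orig$genes$start)
  expect_equal(back$genes$end, orig$genes$end)
  expect_equal(back$genes$strand, orig$genes$strand)
  expect_equal(back$genes$feature_kind, orig$genes$feature_kind)
  expect_equal(back$genes$nt_seq, orig$genes$nt_seq)
  expect_equal(back$genes$aa_seq, orig$genes$aa_seq)
})

test_that("origin-spanning two-segment joins are parsed; other joins rejected", {
  seqs <- paste0(strrep("ACGT", 20), "ATGAAA")  # 86 bp; CDS wraps 81..86 + 1..3
  gb <- c(
    "LOCUS       wraptest                86 bp    DNA     circular BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..86",
    "     CDS             join(81..86,1..3)",
    '                     /locus_tag="w1"',
    "ORIGIN",
    paste0("        1 ", tolower(seqs)),
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  g <- load_genome(path, format = "genbank")
  expect_equal(g$genes$nt_seq[1], paste0(substr(seqs, 81, 86), substr(seqs, 1, 3)))

  gb2 <- sub("join\\(81\\.\\.86,1\\.\\.3\\)", "join(10..15,30..35)", gb)
  writeLines(gb2, path)
  expect_error(load_genome(path, format = "genbank"), "origin-spanning")
})

test_that("multi-record files are rejected with the record count", {
  path <- withr::local_tempfile(fileext = ".gbk")
  rec <- c("LOCUS       r1                9 bp    DNA     circular BCT",
           "FEATURES             Location/Qualifiers",
           "     source          1..9",
           "ORIGIN", "        1 atgaaataa", "//")
  writeLines(c(rec, sub("r1", "r2", rec)), path)
  expect_error(load_genome(path, format = "genbank"), "found 2")
})

test_that("FASTA+GFF3 writing and reloading round-trips the genome", {
  sim <- simulate_pair(small_sim_config(seed = 9, n_backbone = 10, regions = list()))
  fa <- withr::local_tempfile(fileext = ".fna")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(sim$a, format = "gff3", fasta_path = fa, gff_path = gff)
  back <- load_genome(fa, format = "gff3", gff_path = gff)
  expect_equal(back$sequence, sim$a$sequence)
  expect_equal(back$genes$start, sim$a$genes$start)
  expect_equal(back$genes$end, sim$a$genes$end)
  expect_equal(back$genes$strand, sim$a$genes$strand)
  expect_equal(back$genes$aa_seq, sim$a$genes$aa_seq)
})

test_that("marker copy comparison reports minimum edit distances", {
  set.seed(13)
  marker <- random_dna(1500)
  v <- strsplit(marker, "")[[1]]
  pos <- sample(seq_along(v), 3)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  marker3 <- paste(v, collapse = "")

  mk <- function(id, markers) {
    rows <- list(); seq_parts <- character(0); pos <- 0L
    for (i in seq_along(markers)) {
      seq_parts <- c(seq_parts, "ACGTACGTAC", markers[i])
      pos <- pos + 10L
      rows[[i]] <- tibble::tibble(locus_tag = paste0(id, "_rrna", i), start = pos,
                                  end = pos + nchar(markers[i]), strand = "+",
                                  feature_kind = "rRNA",
                                  product = "16S ribosomal RNA")
      pos <- pos + nchar(markers[i])
    }
    new_genome(id, paste(c(seq_parts, "AC"), collapse = ""), dplyr::bind_rows(rows))
  }
  a <- mk("A", c(marker, marker3))
  b <- mk("B", marker)
  res <- compare_marker_copies(a, b)
  expect_equal(sort(res$edit_distance), c(0L, 3L))
  # genome against itself: all distances zero
  expect_true(all(compare_marker_copies(a, a)$edit_distance == 0))
  expect_error(compare_marker_copies(a, b, product_filter = "23S"), "23S")
})
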