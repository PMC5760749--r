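# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(c("M", sample(AA20, n - 1, replace = TRUE)), collapse = "")
}

mutate_protein <- function(p, n_sub) {
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  pos <- sample(seq.int(2, length(v)), n_sub)
  for (i in pos) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

# back-translate a protein into an unbiased in-frame CDS (with stop)
backtranslate <- function(aa) {
  gc11 <- Biostrings::getGeneticCode("11")
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  cods <- vapply(v, function(x) {
    opts <- names(gc11)[gc11 == x]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(cods, collapse = ""), "TAA")
}

# a small genome whose CDS encode the given proteins, all on "+" unless
# stated; spacer of 20 bp between genes
toy_genome_from_proteins <- function(proteins, id = "toy",
                                     strands = rep("+", length(proteins))) {
  nts <- vapply(proteins, backtranslate, character(1))
  pos <- 0L
  rows <- list()
  seq_parts <- character(0)
  for (i in seq_along(nts)) {
    sp <- random_dna(20)
    seq_parts <- c(seq_parts, sp)
    pos <- pos + 20L
    genomic <- if (strands[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(nts[i])))
    } else nts[i]
    seq_parts <- c(seq_parts, genomic)
    rows[[i]] <- tibble::tibble(
      locus_tag = sprintf("%s_%03d", id, i),
      start = pos, end = pos + nchar(nts[i]),
      strand = strands[i], feature_kind = "CDS", product = "protein")
    pos <- pos + nchar(nts[i])
  }
  new_genome(id, paste(c(seq_parts, random_dna(20)), collapse = ""),
             dplyr::bind_rows(rows), source_format = "simulated")
}

# Independent brute-force reverse complement: positional lookup loop.
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(length(v))
  for (i in seq_along(v)) out[length(v) - i + 1] <- comp[[v[i]]]
  paste(out, collapse = "")
}

# Independent single-pass base tally.
oracle_base_tally <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0, other = 0)
  for (ch in v) {
    if (ch %in% names(counts)) counts[ch] <- counts[ch] + 1 else
      counts["other"] <- counts["other"] + 1
  }
  counts
}

# Independent exhaustive best-hit oracle: align every pair with the same
# scoring scheme, walk the alignment strings directly, and apply the
# acceptance rules (score > min_score, both coverages >= min_coverage,
# ties toward the lowest counterpart ordinal).
oracle_pair <- function(p, q) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  paln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(q),
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
    type = "global")
  av <- strsplit(as.character(Biostrings::pattern(paln)), "")[[1]]
  bv <- strsplit(as.character(Biostrings::subject(paln)), "")[[1]]
  gap <- av == "-" | bv == "-"
  keep <- which(cumsum(!gap) > 0 & rev(cumsum(rev(!gap))) > 0)
  tibble::tibble(
    score = Biostrings::score(paln),
    identity = 100 * sum(av[keep] == bv[keep] & !gap[keep]) / length(keep),
    cov_p = sum(av[keep] != "-") / nchar(p),
    cov_q = sum(bv[keep] != "-") / nchar(q))
}

oracle_best_hits <- function(prots_a, prots_b, min_coverage = 0.5, min_score = 0) {
  grid <- expand.grid(ai = seq_along(prots_a), bi = seq_along(prots_b))
  stats <- purrr::pmap(grid, function(ai, bi) {
    cbind(grid[grid$ai == ai & grid$bi == bi, ], oracle_pair(prots_a[ai], prots_b[bi]))
  })
  df <- dplyr::bind_rows(stats)
  ok <- df[df$score > min_score & df$cov_p >= min_coverage & df$cov_q >= min_coverage, ]
  best_of <- function(d, by, counter) {
    out <- list()
    for (g in sort(unique(d[[by]]))) {
      sub <- d[d[[by]] == g, ]
      sub <- sub[order(-sub$score, sub[[counter]]), ]
      out[[length(out) + 1]] <- sub[1, ]
    }
    dplyr::bind_rows(out)
  }
  list(ab = best_of(ok, "ai", "bi"), ba = best_of(ok, "bi", "ai"))
}

# Build an ortholog_map object directly from classification vectors, for
# testing the synteny/region logic in isolation. `cls_*` are tibbles with
# ordinal, class ("bbh"/"unidirectional"/"unique"), counterpart, identity.
fabricate_map <- function(cls_a, cls_b, id_a = "ga", id_b = "gb") {
  bbh_a <- cls_a[cls_a$class == "bbh", ]
  bbh <- tibble::tibble(
    a_ordinal = bbh_a$ordinal, b_ordinal = bbh_a$counterpart,
    a_locus = paste0("a", bbh_a$ordinal), b_locus = paste0("b", bbh_a$counterpart),
    score = 100, aa_identity = bbh_a$identity)
  mk_uni <- function(cls, prefix, cprefix) {
    u <- cls[cls$class == "unidirectional", ]
    tibble::tibble(query_ordinal = u$ordinal, subject_ordinal = u$counterpart,
                   query_locus = paste0(prefix, u$ordinal),
                   subject_locus = paste0(cprefix, u$counterpart),
                   score = 50, aa_identity = u$identity,
                   query_coverage = 1, subject_coverage = 1)
  }
  structure(list(
    bbh = bbh,
    unidirectional_a = mk_uni(cls_a, "a", "b"),
    unidirectional_b = mk_uni(cls_b, "b", "a"),
    unique_a = tibble::tibble(ordinal = cls_a$ordinal[cls_a$class == "unique"],
                              locus_tag = paste0("a", cls_a$ordinal[cls_a$class == "unique"])),
    unique_b = tibble::tibble(ordinal = cls_b$ordinal[cls_b$class == "unique"],
                              locus_tag = paste0("b", cls_b$ordinal[cls_b$class == "unique"])),
    cds_a = tibble::tibble(ordinal = cls_a$ordinal, locus_tag = paste0("a", cls_a$ordinal)),
    cds_b = tibble::tibble(ordinal = cls_b$ordinal, locus_tag = paste0("b", cls_b$ordinal)),
    genome_id_a = id_a, genome_id_b = id_b,
    params = list()), class = "ortholog_map")
}

# small default-structure config scaled down for unit tests
small_sim_config <- function(seed = 1L, n_backbone = 80L,
                             regions = list(list(name = "A", n_genes = 20L,
                                                 n_unique_a = 12L, n_unique_b = 10L,
                                                 donor_tv = 0.4, donor_rank = 1L,
                                                 insert_after = 40L,
                                                 homolog_identity = c(40, 65)))) {
  cfg <- default_pair_config(seed = seed, n_backbone_genes = n_backbone)
  cfg$gene_length_mean <- 150
  cfg$gene_length_sd <- 40
  cfg$planted_regions <- regions
  cfg
}
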