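#' Construct a genome object
#'
#' A `genome` is the package's in-memory model of one annotated bacterial
#' replicon: the chromosome sequence plus an ordered gene table. Gene
#' coordinates are stored 0-based half-open; GenBank and GFF3 readers and
#' writers convert from/to the 1-based inclusive convention of those formats.
#'
#' @param genome_id Single string naming the replicon.
#' @param sequence Nucleotide sequence as a single character string
#'   (alphabet `A`, `C`, `G`, `T`, `N` and IUPAC ambiguity codes).
#' @param genes Data frame with one row per annotated feature and columns
#'   `locus_tag`, `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `feature_kind` (`"CDS"`, `"rRNA"`, `"tRNA"`, `"other_RNA"`) and
#'   `product`. Optional logical column `partial` marks CDS whose length is
#'   not a multiple of 3; they are kept but excluded from protein analyses.
#' @param source_format Provenance tag, `"genbank"`, `"fasta+gff3"` or
#'   `"simulated"`.
#'
#' @details Gene ordinals (`0..n-1`) are assigned in start-coordinate order.
#'   CDS nucleotide sequences are extracted strand-corrected (reverse
#'   strand features are reverse-complemented) and translated with the
#'   bacterial genetic code (table 11); annotated alternative starts
#'   (GTG/TTG) are rendered as M.
#'
#' @return An object of class `genome`.
#' @export
new_genome <- function(genome_id, sequence, genes, source_format = "simulated") {
  sequence <- toupper(sequence)
  genes <- as_tibble(genes)
  required <- c("locus_tag", "start", "end", "strand", "feature_kind", "product")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("genes table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) > 0) {
    if (any(genes$end <= genes$start)) {
      abort("gene intervals must satisfy end > start (0-based half-open)")
    }
    if (any(genes$start < 0) || any(genes$end > nchar(sequence))) {
      abort("gene interval outside the replicon sequence")
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
  }
  if (!"partial" %in% names(genes)) genes$partial <- FALSE
  if (!"wrap_extra" %in% names(genes)) genes$wrap_extra <- 0L
  if (any(genes$wrap_extra > 0 & genes$end != nchar(sequence))) {
    abort("origin-spanning features must end at the replicon end")
  }
  genes <- genes |>
    arrange(.data$start, .data$end) |>
    mutate(ordinal = row_number() - 1L)

  # strand-corrected nucleotide sequence and translation for CDS;
  # wrap_extra > 0 marks origin-spanning features whose tail continues
  # from base 1
  nt <- character(nrow(genes))
  aa <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- substr(sequence, genes$start[i] + 1L, genes$end[i])
    if (genes$wrap_extra[i] > 0) {
      s <- paste0(s, substr(sequence, 1L, genes$wrap_extra[i]))
    }
    if (genes$strand[i] == "-") s <- reverse_complement(s)
    nt[i] <- s
    if (genes$feature_kind[i] == "CDS") {
      if (nchar(s) %% 3 != 0) {
        genes$partial[i] <- TRUE
        warn(paste0("CDS ", genes$locus_tag[i],
                    " length not divisible by 3; flagged partial and excluded from protein analyses"))
      } else {
        aa[i] <- translate_cds(s)
      }
    }
  }
  genes$nt_seq <- nt
  genes$aa_seq <- aa
  genes <- genes |>
    select("locus_tag", "ordinal", "start", "end", "strand", "feature_kind",
           "product", "partial", "wrap_extra", "nt_seq", "aa_seq")

  structure(
    list(genome_id = genome_id, sequence = sequence, genes = genes,
         source_format = source_format),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, "\n", sep = "")
  cat("  sequence: ", format(nchar(x$sequence), big.mark = ","), " bp, GC ",
      sprintf("%.1f%%", gc_percent(x$sequence)), "\n", sep = "")
  kinds <- table(x$genes$feature_kind)
  cat("  features: ", nrow(x$genes), " (",
      paste(names(kinds), as.integer(kinds), collapse = ", "), ")\n", sep = "")
  cat("  source:   ", x$source_format, "\n", sep = "")
  invisible(x)
}

is_genome <- function(x) inherits(x, "genome")

#' Extract the proteome of a genome
#'
#' Returns the amino-acid sequences of all complete (non-partial) CDS
#' features, named by locus tag, as an [Biostrings::AAStringSet].
#'
#' @param genome A `genome` object.
#' @return An `AAStringSet`; `mcols()`-free, names are locus tags.
#' @export
proteome <- function(genome) {
  stopifnot(is_genome(genome))
  cds <- genome$genes |> filter(.data$feature_kind == "CDS", !.data$partial)
  Biostrings::AAStringSet(setNames(cds$aa_seq, cds$locus_tag))
}

#' Summarize an annotated genome
#'
#' Sequence- and annotation-derived summary statistics for one genome:
#' length, GC content, and feature counts by kind, including the number of
#' CDS whose product is annotated as a hypothetical protein (case-insensitive
#' substring match on the product text).
#'
#' @param genome A `genome` object.
#' @return A one-row tibble with columns `genome_id`, `length_bp`,
#'   `gc_percent`, `n_genes`, `n_cds`, `n_trna`, `n_rrna`, `n_other_rna`,
#'   `n_hypothetical`.
#' @export
#' @examples
#' g <- new_genome("toy", "ATGAAATAAGGCC",
#'   tibble::tibble(locus_tag = "g1", start = 0, end = 9, strand = "+",
#'                  feature_kind = "CDS", product = "hypothetical protein"))
#' summarize_genome(g)
summarize_genome <- function(genome) {
  stopifnot(is_genome(genome))
  if (nchar(genome$sequence) == 0) abort("genome has an empty sequence")
  g <- genome$genes
  tibble(
    genome_id = genome$genome_id,
    length_bp = nchar(genome$sequence),
    gc_percent = round(gc_percent(genome$sequence), 1),
    n_genes = nrow(g),
    n_cds = sum(g$feature_kind == "CDS"),
    n_trna = sum(g$feature_kind == "tRNA"),
    n_rrna = sum(g$feature_kind == "rRNA"),
    n_other_rna = sum(g$feature_kind == "other_RNA"),
    n_hypothetical = sum(g$feature_kind == "CDS" &
                           grepl("hypothetical protein", g$product, ignore.case = TRUE))
  )
}

#' Compare marker gene copies between two genomes
#'
#' For every copy of a marker feature (for example the 16S rRNA gene) in
#' genome `a`, computes the minimum edit distance (global alignment, unit
#' costs for substitutions and indels) to any copy in genome `b`. Used to
#' check strain identity, e.g. two 16S copies at distances 0 and 1 from the
#' type strain.
#'
#' @param a,b `genome` objects.
#' @param feature_kind Feature kind to match, default `"rRNA"`.
#' @param product_filter Case-insensitive substring the product text must
#'   contain, default `"16S"`.
#' @return A tibble with one row per copy in `a`: `a_locus`, `b_locus` (the
#'   closest copy in `b`), `edit_distance`.
#' @export
compare_marker_copies <- function(a, b, feature_kind = "rRNA", product_filter = "16S") {
  stopifnot(is_genome(a), is_genome(b))
  pick <- function(g) {
    g$genes |>
      filter(.data$feature_kind == !!feature_kind,
             grepl(product_filter, .data$product, ignore.case = TRUE))
  }
  ca <- pick(a)
  cb <- pick(b)
  if (nrow(ca) == 0 || nrow(cb) == 0) {
    abort(paste0("no feature of kind '", feature_kind, "' with product matching '",
                 product_filter, "' in ", if (nrow(ca) == 0) a$genome_id else b$genome_id))
  }
  d <- adist(ca$nt_seq, cb$nt_seq)
  j <- apply(d, 1, which.min)
  tibble(
    a_locus = ca$locus_tag,
    b_locus = cb$locus_tag[j],
    edit_distance = as.integer(d[cbind(seq_len(nrow(ca)), j)])
  )
}
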