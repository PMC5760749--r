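#' Load an annotated genome
#'
#' Reads a single-replicon annotated bacterial genome either from a GenBank
#' flat file or from a FASTA sequence plus a GFF3 annotation. The result is
#' the package's internal `genome` model (see [new_genome()]): coordinates
#' 0-based half-open, gene ordinals assigned in start-coordinate order, CDS
#' translated with the bacterial genetic code (table 11).
#'
#' @param path Path to the GenBank file, or to the FASTA file when
#'   `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param gff_path Path to the GFF3 file (required for `format = "gff3"`).
#'
#' @details Multi-record files are rejected with an error naming the record
#'   count ("one chromosome and no plasmids" is the expected input). CDS
#'   whose length is not a multiple of 3 are flagged partial, kept in the
#'   gene table, and excluded from protein-level analyses with a warning.
#'
#' @return A `genome` object.
#' @export
load_genome <- function(path, format = c("genbank", "gff3"), gff_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "genbank") {
    return(read_genbank(path))
  }
  if (is.null(gff_path)) abort("format 'gff3' requires `gff_path`")
  if (!file.exists(gff_path)) abort(paste0("file not found: ", gff_path))
  read_fasta_gff3(path, gff_path)
}

read_fasta_gff3 <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1) {
    abort(paste0("expected exactly one record, found ", length(seqs),
                 " in ", fasta_path))
  }
  seq_id <- strsplit(names(seqs)[1], " +")[[1]][1]

  gff <- rtracklayer::import(gff_path, format = "gff3")
  kind_map <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                ncRNA = "other_RNA", tmRNA = "other_RNA", misc_RNA = "other_RNA")
  gff <- gff[as.character(gff$type) %in% names(kind_map)]
  md <- as.data.frame(gff)
  seqids <- unique(as.character(md$seqnames))
  if (!all(seqids == seq_id)) {
    abort(paste0("GFF3 seqid (", paste(seqids, collapse = ","),
                 ") does not match FASTA header (", seq_id, ")"))
  }
  locus <- if ("locus_tag" %in% names(md)) md$locus_tag else md$ID
  if (is.null(locus)) locus <- paste0("feat_", seq_len(nrow(md)))
  genes <- tibble(
    locus_tag = as.character(locus),
    start = as.integer(md$start) - 1L,   # GFF3 is 1-based inclusive
    end = as.integer(md$end),
    strand = ifelse(as.character(md$strand) == "-", "-", "+"),
    feature_kind = unname(kind_map[as.character(md$type)]),
    product = if ("product" %in% names(md)) {
      ifelse(is.na(md$product), "", as.character(md$product))
    } else "",
  )
  new_genome(seq_id, as.character(seqs[[1]]), genes, source_format = "fasta+gff3")
}

#' Write a genome as FASTA + GFF3 (or GenBank)
#'
#' Serialises a `genome` object to disk. FASTA/GFF3 output is the inverse of
#' `load_genome(format = "gff3")`; GenBank output is the inverse of
#' `load_genome(format = "genbank")`.
#'
#' @param genome A `genome` object.
#' @param fasta_path,gff_path Output paths for `format = "gff3"`.
#' @param path Output path for `format = "genbank"`.
#' @param format `"gff3"` or `"genbank"`.
#' @return Invisibly, the main output path.
#' @export
write_genome <- function(genome, format = c("gff3", "genbank"),
                         fasta_path = NULL, gff_path = NULL, path = NULL) {
  stopifnot(is_genome(genome))
  format <- match.arg(format)
  if (format == "genbank") {
    if (is.null(path)) abort("format 'genbank' requires `path`")
    return(invisible(write_genbank(genome, path)))
  }
  if (is.null(fasta_path) || is.null(gff_path)) {
    abort("format 'gff3' requires `fasta_path` and `gff_path`")
  }
  writeLines(c(paste0(">", genome$genome_id),
               substring(genome$sequence,
                         seq(1, nchar(genome$sequence), 70),
                         pmin(seq(70, nchar(genome$sequence) + 69, 70),
                              nchar(genome$sequence)))),
             fasta_path)
  g <- genome$genes
  type_map <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", other_RNA = "misc_RNA")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$genome_id,
                     nchar(genome$sequence)),
             sprintf("%s\tgenomepair\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;locus_tag=%s%s",
                     genome$genome_id, type_map[g$feature_kind],
                     g$start + 1L, g$end, g$strand,
                     ifelse(g$feature_kind == "CDS", "0", "."),
                     g$locus_tag, g$locus_tag,
                     ifelse(nzchar(g$product),
                            paste0(";product=", gsub("[;=\t]", " ", g$product)), "")))
  writeLines(lines, gff_path)
  invisible(fasta_path)
}
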