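# GenBank flat-file reading and writing.
#
# Scope: single-replicon bacterial records; features CDS/rRNA/tRNA plus the
# common RNA keys (ncRNA, tmRNA, misc_RNA mapped to other_RNA). Locations
# `a..b`, `complement(a..b)` and two-segment origin-spanning
# `join(a..len,1..b)`; any other join is rejected. Coordinates convert
# between GenBank 1-based inclusive and the internal 0-based half-open
# convention.

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_records <- sum(grepl("^LOCUS ", lines))
  if (n_records == 0) abort(paste0("no LOCUS line found in ", path))
  if (n_records > 1) {
    abort(paste0("expected exactly one record, found ", n_records, " in ", path))
  }

  locus_line <- lines[grepl("^LOCUS ", lines)][1]
  genome_id <- strsplit(trimws(sub("^LOCUS +", "", locus_line)), " +")[[1]][1]

  feat_start <- grep("^FEATURES", lines)[1]
  origin_start <- grep("^ORIGIN", lines)[1]
  if (is.na(feat_start) || is.na(origin_start)) {
    abort("malformed GenBank record: missing FEATURES or ORIGIN section")
  }

  seq_lines <- lines[(origin_start + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_lines <- lines[(feat_start + 1):(origin_start - 1)]
  genes <- parse_genbank_features(feat_lines, nchar(sequence))

  new_genome(genome_id, sequence, genes, source_format = "genbank")
}

parse_genbank_features <- function(feat_lines, seq_length) {
  # a new feature starts at column 6; qualifiers/continuations at column 22
  is_new <- grepl("^ {5}\\S", feat_lines)
  idx <- which(is_new)
  out <- list()
  kind_map <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                ncRNA = "other_RNA", tmRNA = "other_RNA", misc_RNA = "other_RNA")

  for (k in seq_along(idx)) {
    first <- idx[k]
    last <- if (k < length(idx)) idx[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[first:last]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (!key %in% names(kind_map)) next

    # location may continue over lines until the first qualifier line
    qual_at <- grep("^ +/", block)
    loc_end <- if (length(qual_at) > 0) qual_at[1] - 1 else length(block)
    loc_lines <- block[seq_len(loc_end)]
    loc <- paste0(trimws(sub("^ {5}\\S+ +", "", loc_lines[1])),
                  paste(trimws(loc_lines[-1]), collapse = ""))
    loc <- gsub(" ", "", loc)
    parsed <- parse_genbank_location(loc, seq_length)

    quals <- parse_genbank_qualifiers(block[seq_along(block) >= loc_end + 1])
    out[[length(out) + 1]] <- tibble(
      locus_tag = quals[["locus_tag"]] %||% quals[["gene"]] %||%
        paste0("feat_", length(out) + 1),
      start = parsed$start, end = parsed$end,
      strand = parsed$strand, feature_kind = unname(kind_map[key]),
      product = quals[["product"]] %||% "",
      partial = parsed$partial, wrap_extra = parsed$wrap_extra
    )
  }
  if (length(out) == 0) {
    return(tibble(locus_tag = character(), start = integer(), end = integer(),
                  strand = character(), feature_kind = character(),
                  product = character(), partial = logical(),
                  wrap_extra = integer()))
  }
  bind_rows(out)
}

parse_genbank_location <- function(loc, seq_length) {
  strand <- "+"
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wrap_extra <- 0L
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(segs) != 2) {
      abort(paste0("unsupported join with ", length(segs),
                   " segments; only two-segment origin-spanning joins are supported"))
    }
    s1 <- parse_span(segs[1])
    s2 <- parse_span(segs[2])
    if (s1[2] != seq_length || s2[1] != 1) {
      abort("unsupported join: only origin-spanning join(a..len,1..b) is handled")
    }
    return(list(start = s1[1] - 1L, end = s1[2], strand = strand,
                partial = partial, wrap_extra = as.integer(s2[2])))
  }
  s <- parse_span(loc)
  list(start = s[1] - 1L, end = s[2], strand = strand,
       partial = partial, wrap_extra = wrap_extra)
}

parse_span <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse location '", x, "'"))
  c(as.integer(m[2]), as.integer(m[3]))
}

parse_genbank_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  txt <- trimws(lines)
  starts <- grepl("^/", txt)
  if (!any(starts)) return(list())
  grp <- cumsum(starts)
  quals <- list()
  for (g in unique(grp[starts])) {
    piece <- paste(txt[grp == g], collapse = " ")
    m <- regmatches(piece, regexec('^/([A-Za-z_]+)=?"?(.*?)"?$', piece))[[1]]
    if (length(m) == 3 && nzchar(m[2])) quals[[m[2]]] <- m[3]
  }
  quals
}

write_genbank <- function(genome, path) {
  stopifnot(is_genome(genome))
  slen <- nchar(genome$sequence)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %9d bp    DNA     circular BCT",
                     genome$genome_id, slen), con)
  writeLines(sprintf("DEFINITION  %s, complete genome.", genome$genome_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", slen), con)
  kind_key <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", other_RNA = "misc_RNA")
  g <- genome$genes
  wrap <- if ("wrap_extra" %in% names(g)) g$wrap_extra else rep(0L, nrow(g))
  for (i in seq_len(nrow(g))) {
    loc <- if (wrap[i] > 0) {
      sprintf("join(%d..%d,1..%d)", g$start[i] + 1L, g$end[i], wrap[i])
    } else {
      sprintf("%d..%d", g$start[i] + 1L, g$end[i])
    }
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", kind_key[[g$feature_kind[i]]], loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', g$locus_tag[i]), con)
    if (nzchar(g$product[i])) {
      writeLines(sprintf('                     /product="%s"', g$product[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  pos <- seq(1, slen, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, slen))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
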