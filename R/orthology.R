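# Best-hit orthology between two proteomes.
#
# Scoring is global (end-to-end) protein alignment with affine gaps under
# BLOSUM62 (open 11, extend 1). Percent identity is computed over alignment
# columns excluding terminal gap runs, so a truncated counterpart is not
# penalised for missing ends. Candidate pairs may be shortlisted by a
# k-mer screen (the installed blastp, or a built-in shared k-mer filter);
# the screen only limits which pairs are rescored -- ranking and acceptance
# always use the package's own global alignment.

default_alignment_params <- function() {
  list(gap_opening = 11, gap_extension = 1,
       min_coverage = 0.5, min_score = 0,
       prefilter = "auto", kmer_k = 4L, kmer_min_shared = 1L,
       blast_evalue = 1e-3, blast_max_targets = 25L)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Globally align two protein sequences
#'
#' Needleman-Wunsch alignment with affine gap penalties under BLOSUM62
#' (gap open 11, gap extend 1). Amino-acid identity is the fraction of
#' identical columns among alignment columns excluding terminal gap runs,
#' expressed as a percent; coverages are the fraction of each sequence
#' inside the non-terminal-gap region.
#'
#' @param p,q Protein sequences (single character strings; `X` permitted).
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @return A one-row tibble: `score`, `aa_identity`, `query_coverage`,
#'   `subject_coverage`, `n_columns`.
#' @export
#' @examples
#' align_pair("MKT", "MRT")$aa_identity  # 66.7: 2 of 3 columns identical
align_pair <- function(p, q, gap_opening = 11, gap_extension = 1) {
  if (!nzchar(p) || !nzchar(q)) abort("align_pair requires non-empty sequences")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(q),
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global"
  )
  stats <- alignment_column_stats(
    as.character(Biostrings::pattern(pa)),
    as.character(Biostrings::subject(pa))
  )
  tibble(
    score = Biostrings::score(pa),
    aa_identity = stats$identity,
    query_coverage = stats$res_p / nchar(p),
    subject_coverage = stats$res_q / nchar(q),
    n_columns = stats$n_columns
  )
}

# Column bookkeeping on a pair of aligned (gapped) strings: drop terminal
# gap runs, then count identical columns and residues of each sequence
# within the retained window.
alignment_column_stats <- function(astr, bstr) {
  av <- strsplit(astr, "", fixed = TRUE)[[1]]
  bv <- strsplit(bstr, "", fixed = TRUE)[[1]]
  gap <- av == "-" | bv == "-"
  n <- length(av)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- if (n - lead - trail > 0) seq.int(lead + 1L, n - trail) else integer(0)
  n_cols <- length(keep)
  ident <- sum(av[keep] == bv[keep] & !gap[keep])
  list(
    identity = if (n_cols > 0) 100 * ident / n_cols else 0,
    n_columns = n_cols,
    res_p = sum(av[keep] != "-"),
    res_q = sum(bv[keep] != "-")
  )
}

#' Compute best-hit tables between two proteomes
#'
#' For every complete CDS of each genome, finds the highest-scoring
#' counterpart in the other genome that passes the minimum score and
#' coverage thresholds (or none). Ties on score are broken toward the
#' lowest counterpart ordinal, so results are deterministic.
#'
#' @param a,b `genome` objects with at least one CDS each.
#' @param params Alignment/threshold settings, see
#'   [default_alignment_params()]. `prefilter` is one of `"auto"` (blastp
#'   when available, else the built-in k-mer screen), `"blast"`, `"kmer"`,
#'   `"none"` (exhaustive all-vs-all).
#' @return An object of class `hit_tables`: a list with tibbles `hits_ab`
#'   and `hits_ba` (`query_ordinal`, `subject_ordinal`, loci, `score`,
#'   `aa_identity`, `query_coverage`, `subject_coverage`).
#' @export
best_hits <- function(a, b, params = default_alignment_params()) {
  stopifnot(is_genome(a), is_genome(b))
  params <- utils::modifyList(default_alignment_params(), params)
  pa <- proteome(a)
  pb <- proteome(b)
  if (length(pa) == 0 || length(pb) == 0) {
    abort("both genomes must contain at least one complete CDS")
  }
  ord_a <- cds_ordinals(a)
  ord_b <- cds_ordinals(b)

  cand <- candidate_pairs(pa, pb, params)   # tibble(ai, bi), indexes into pa/pb
  scores <- score_candidates(pa, pb, cand, params)

  cache <- new.env(parent = emptyenv())
  hits_ab <- pick_best(scores, pa, pb, ord_a, ord_b, params, cache,
                       direction = "ab")
  hits_ba <- pick_best(scores, pa, pb, ord_a, ord_b, params, cache,
                       direction = "ba")
  structure(
    list(hits_ab = hits_ab, hits_ba = hits_ba,
         cds_a = tibble(ordinal = ord_a, locus_tag = names(pa)),
         cds_b = tibble(ordinal = ord_b, locus_tag = names(pb)),
         genome_id_a = a$genome_id, genome_id_b = b$genome_id,
         params = params),
    class = "hit_tables"
  )
}

cds_ordinals <- function(genome) {
  cds <- genome$genes |> filter(.data$feature_kind == "CDS", !.data$partial)
  cds$ordinal
}

candidate_pairs <- function(pa, pb, params) {
  pf <- params$prefilter
  if (pf == "auto") {
    pf <- if (nzchar(Sys.which("blastp"))) "blast" else "kmer"
  }
  switch(pf,
    none = tidyr::expand_grid(ai = seq_along(pa), bi = seq_along(pb)),
    kmer = candidate_pairs_kmer(pa, pb, params$kmer_k, params$kmer_min_shared),
    blast = candidate_pairs_blast(pa, pb, params),
    abort(paste0("unknown prefilter '", pf, "'"))
  )
}

candidate_pairs_kmer <- function(pa, pb, k, min_shared) {
  kmers <- function(seqs) {
    purrr::imap(as.character(seqs), function(s, i) {
      n <- nchar(s)
      if (n < k) return(tibble(kmer = character(), i = integer()))
      tibble(kmer = unique(substring(s, 1:(n - k + 1), k:n)))
    }) |>
      bind_rows(.id = "idx") |>
      mutate(idx = as.integer(.data$idx))
  }
  ka <- kmers(setNames(as.character(pa), seq_along(pa)))
  kb <- kmers(setNames(as.character(pb), seq_along(pb)))
  inner_join(ka, kb, by = "kmer", relationship = "many-to-many") |>
    dplyr::count(ai = .data$idx.x, bi = .data$idx.y) |>
    filter(.data$n >= min_shared) |>
    select("ai", "bi")
}

candidate_pairs_blast <- function(pa, pb, params) {
  if (!nzchar(Sys.which("blastp")) || !nzchar(Sys.which("makeblastdb"))) {
    abort("blastp/makeblastdb not found on PATH; use prefilter = 'kmer' or 'none'")
  }
  dir <- tempfile("gp_blast_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa_a <- file.path(dir, "a.faa")
  fa_b <- file.path(dir, "b.faa")
  Biostrings::writeXStringSet(setNames(pa, paste0("q", seq_along(pa))), fa_a)
  Biostrings::writeXStringSet(setNames(pb, paste0("s", seq_along(pb))), fa_b)
  run_quiet <- function(cmd, args) {
    out <- system2(cmd, args, stdout = TRUE, stderr = TRUE)
    status <- attr(out, "status") %||% 0L
    if (status != 0) abort(paste0(cmd, " failed: ", paste(out, collapse = "\n")))
    out
  }
  one_way <- function(query, dbfa, qtag, stag) {
    db <- file.path(dir, paste0("db_", stag))
    run_quiet("makeblastdb", c("-in", dbfa, "-dbtype", "prot", "-out", db))
    tab <- file.path(dir, paste0("hits_", qtag, ".tsv"))
    run_quiet("blastp", c("-query", query, "-db", db,
                          "-outfmt", shQuote("6 qseqid sseqid"),
                          "-evalue", format(params$blast_evalue),
                          "-max_target_seqs", params$blast_max_targets,
                          "-seg", "no", "-out", tab))
    if (file.size(tab) == 0) {
      return(tibble(q = character(), s = character()))
    }
    readr::read_tsv(tab, col_names = c("q", "s"), col_types = "cc",
                    progress = FALSE)
  }
  fwd <- one_way(fa_a, fa_b, "a", "b")
  rev <- one_way(fa_b, fa_a, "b", "a")
  bind_rows(
    fwd |> mutate(ai = as.integer(sub("^q", "", .data$q)),
                  bi = as.integer(sub("^s", "", .data$s))),
    rev |> mutate(ai = as.integer(sub("^q", "", .data$s)),
                  bi = as.integer(sub("^s", "", .data$q)))
  ) |>
    distinct(.data$ai, .data$bi)
}

# Global alignment score for every candidate pair, in one batched
# elementwise call to the C alignment engine.
score_candidates <- function(pa, pb, cand, params) {
  if (nrow(cand) == 0) {
    return(tibble(ai = integer(), bi = integer(), score = numeric()))
  }
  sc <- Biostrings::pairwiseAlignment(
    pa[cand$ai], pb[cand$bi],
    substitutionMatrix = blosum62(),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    type = "global", scoreOnly = TRUE
  )
  tibble(ai = cand$ai, bi = cand$bi, score = sc)
}

# Traceback stats for candidate pairs, cached in canonical a-b
# orientation: cov_a / cov_b are the fraction of each sequence inside the
# non-terminal-gap window. Uncached pairs are aligned in one batched
# (elementwise) call.
batch_pair_stats <- function(ai, bi, pa, pb, params, cache) {
  keys <- paste0(ai, "_", bi)
  todo <- which(!vapply(keys, function(k) !is.null(cache[[k]]), logical(1)))
  if (length(todo) > 0) {
    paln <- Biostrings::pairwiseAlignment(
      pa[ai[todo]], pb[bi[todo]],
      substitutionMatrix = blosum62(),
      gapOpening = params$gap_opening, gapExtension = params$gap_extension,
      type = "global"
    )
    astr <- as.character(Biostrings::pattern(paln))
    bstr <- as.character(Biostrings::subject(paln))
    wa <- Biostrings::width(pa)[ai[todo]]
    wb <- Biostrings::width(pb)[bi[todo]]
    for (j in seq_along(todo)) {
      raw <- alignment_column_stats(astr[j], bstr[j])
      cache[[keys[todo[j]]]] <- list(identity = raw$identity,
                                     cov_a = raw$res_p / wa[j],
                                     cov_b = raw$res_q / wb[j])
    }
  }
  lapply(keys, function(k) cache[[k]])
}

# Walk each query's candidates in score order (ties toward the lowest
# counterpart ordinal) and accept the first that passes score and coverage
# thresholds after full traceback. Tracebacks are run in batched rounds:
# in each round every unresolved query contributes its current top
# candidate.
pick_best <- function(scores, pa, pb, ord_a, ord_b, params, cache, direction) {
  empty <- tibble(query_ordinal = integer(), subject_ordinal = integer(),
                  query_locus = character(), subject_locus = character(),
                  score = numeric(), aa_identity = numeric(),
                  query_coverage = numeric(), subject_coverage = numeric())
  if (direction == "ab") {
    df <- scores |> mutate(qi = .data$ai, si = .data$bi, s_ord = ord_b[.data$bi])
  } else {
    df <- scores |> mutate(qi = .data$bi, si = .data$ai, s_ord = ord_a[.data$ai])
  }
  df <- df |>
    filter(.data$score > params$min_score) |>
    arrange(.data$qi, dplyr::desc(.data$score), .data$s_ord) |>
    group_by(.data$qi) |>
    mutate(rank = row_number()) |>
    ungroup()
  if (nrow(df) == 0) return(empty)

  rows <- list()
  pointer <- setNames(rep(1L, length(unique(df$qi))), unique(df$qi))
  repeat {
    active <- df |>
      filter(.data$rank == pointer[as.character(.data$qi)])
    if (nrow(active) == 0) break
    stats <- if (direction == "ab") {
      batch_pair_stats(active$qi, active$si, pa, pb, params, cache)
    } else {
      batch_pair_stats(active$si, active$qi, pa, pb, params, cache)
    }
    resolved <- character(0)
    for (j in seq_len(nrow(active))) {
      st <- stats[[j]]
      if (direction == "ab") {
        qcov <- st$cov_a; scov <- st$cov_b
      } else {
        qcov <- st$cov_b; scov <- st$cov_a
      }
      q <- active$qi[j]; s <- active$si[j]
      if (qcov >= params$min_coverage && scov >= params$min_coverage) {
        rows[[length(rows) + 1]] <- if (direction == "ab") {
          tibble(query_ordinal = ord_a[q], subject_ordinal = ord_b[s],
                 query_locus = names(pa)[q], subject_locus = names(pb)[s],
                 score = active$score[j], aa_identity = st$identity,
                 query_coverage = qcov, subject_coverage = scov)
        } else {
          tibble(query_ordinal = ord_b[q], subject_ordinal = ord_a[s],
                 query_locus = names(pb)[q], subject_locus = names(pa)[s],
                 score = active$score[j], aa_identity = st$identity,
                 query_coverage = qcov, subject_coverage = scov)
        }
        resolved <- c(resolved, as.character(q))
      } else {
        pointer[as.character(q)] <- pointer[as.character(q)] + 1L
      }
    }
    pointer <- pointer[!names(pointer) %in% resolved]
    if (length(pointer) == 0) break
    df <- df |> filter(as.character(.data$qi) %in% names(pointer))
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(.data$query_ordinal)
}
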