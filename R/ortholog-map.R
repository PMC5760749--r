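#' Classify genes from reciprocal best-hit tables
#'
#' Combines the two directional best-hit tables into an ortholog map:
#' a pair is a bidirectional best hit (BBH) iff each gene is the other's
#' best hit; a gene is a unidirectional best hit iff it has an accepted best
#' hit that is not reciprocated; and unique iff no hit passed the
#' thresholds.
#'
#' @param hits A `hit_tables` object from [best_hits()].
#' @return An object of class `ortholog_map`: list with `bbh` (tibble
#'   `a_ordinal`, `b_ordinal`, `a_locus`, `b_locus`, `aa_identity`,
#'   `score`), `unidirectional_a`, `unidirectional_b` (hit tibbles),
#'   `unique_a`, `unique_b` (tibbles of ordinal + locus), and the CDS
#'   tables of both genomes.
#' @export
classify_hits <- function(hits) {
  stopifnot(inherits(hits, "hit_tables"))
  ab <- hits$hits_ab
  ba <- hits$hits_ba

  bbh <- inner_join(
    ab |> select(a_ordinal = "query_ordinal", b_ordinal = "subject_ordinal",
                 a_locus = "query_locus", b_locus = "subject_locus",
                 "score", "aa_identity"),
    ba |> select(b_ordinal = "query_ordinal", a_ordinal = "subject_ordinal"),
    by = c("a_ordinal", "b_ordinal")
  ) |>
    arrange(.data$a_ordinal)

  uni_a <- ab |> filter(!.data$query_ordinal %in% bbh$a_ordinal)
  uni_b <- ba |> filter(!.data$query_ordinal %in% bbh$b_ordinal)
  unique_a <- hits$cds_a |>
    filter(!.data$ordinal %in% c(bbh$a_ordinal, uni_a$query_ordinal))
  unique_b <- hits$cds_b |>
    filter(!.data$ordinal %in% c(bbh$b_ordinal, uni_b$query_ordinal))

  structure(
    list(bbh = bbh, unidirectional_a = uni_a, unidirectional_b = uni_b,
         unique_a = unique_a, unique_b = unique_b,
         cds_a = hits$cds_a, cds_b = hits$cds_b,
         genome_id_a = hits$genome_id_a, genome_id_b = hits$genome_id_b,
         params = hits$params),
    class = "ortholog_map"
  )
}

#' Map orthologs between two genomes
#'
#' Convenience wrapper: [best_hits()] followed by [classify_hits()].
#'
#' @inheritParams best_hits
#' @return An `ortholog_map`; see [classify_hits()].
#' @export
ortholog_map <- function(a, b, params = default_alignment_params()) {
  classify_hits(best_hits(a, b, params))
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("<ortholog_map> ", x$genome_id_a, " vs ", x$genome_id_b, "\n", sep = "")
  cat("  BBH pairs:      ", nrow(x$bbh), "\n", sep = "")
  cat("  unidirectional: ", nrow(x$unidirectional_a), " (a), ",
      nrow(x$unidirectional_b), " (b)\n", sep = "")
  cat("  unique:         ", nrow(x$unique_a), " (a), ",
      nrow(x$unique_b), " (b)\n", sep = "")
  invisible(x)
}

#' Per-gene classification of an ortholog map
#'
#' @param x An `ortholog_map`.
#' @param ... Unused.
#' @return A tibble with one row per CDS of both genomes: `genome`
#'   (`"a"`/`"b"`), `ordinal`, `locus_tag`, `class` (`"bbh"`,
#'   `"unidirectional"`, `"unique"`), `counterpart_ordinal`, `aa_identity`.
#' @method tidy ortholog_map
#' @export
tidy.ortholog_map <- function(x, ...) {
  side <- function(which) {
    cds <- if (which == "a") x$cds_a else x$cds_b
    bbh_ord <- if (which == "a") x$bbh$a_ordinal else x$bbh$b_ordinal
    bbh_cp <- if (which == "a") x$bbh$b_ordinal else x$bbh$a_ordinal
    uni <- if (which == "a") x$unidirectional_a else x$unidirectional_b
    cds |>
      mutate(genome = which,
             class = dplyr::case_when(
               .data$ordinal %in% bbh_ord ~ "bbh",
               .data$ordinal %in% uni$query_ordinal ~ "unidirectional",
               TRUE ~ "unique"),
             counterpart_ordinal = dplyr::coalesce(
               bbh_cp[match(.data$ordinal, bbh_ord)],
               uni$subject_ordinal[match(.data$ordinal, uni$query_ordinal)]),
             aa_identity = dplyr::coalesce(
               x$bbh$aa_identity[match(.data$ordinal, bbh_ord)],
               uni$aa_identity[match(.data$ordinal, uni$query_ordinal)])) |>
      select("genome", "ordinal", "locus_tag", "class",
             "counterpart_ordinal", "aa_identity")
  }
  bind_rows(side("a"), side("b"))
}

#' One-row summary of an ortholog map
#'
#' @param x An `ortholog_map`.
#' @param ... Unused.
#' @return A one-row tibble with BBH/unidirectional/unique counts and the
#'   number of BBH pairs below 70% amino-acid identity.
#' @method glance ortholog_map
#' @export
glance.ortholog_map <- function(x, ...) {
  tibble(
    n_cds_a = nrow(x$cds_a), n_cds_b = nrow(x$cds_b),
    n_bbh = nrow(x$bbh),
    n_unidirectional_a = nrow(x$unidirectional_a),
    n_unidirectional_b = nrow(x$unidirectional_b),
    n_unique_a = nrow(x$unique_a), n_unique_b = nrow(x$unique_b),
    n_bbh_lt70 = sum(x$bbh$aa_identity < 70)
  )
}

#' Cumulative identity distribution of BBH pairs
#'
#' For each identity threshold, the count and fraction of bidirectional
#' best hits with amino-acid identity at or above the threshold (e.g. "86%
#' of BBHs have at least 98% identity"), plus the size of the < 70% tail.
#'
#' @param map An `ortholog_map` with at least one BBH pair.
#' @param thresholds Identity thresholds in percent.
#' @return A tibble `threshold`, `n_ge`, `frac_ge`, with the `< 70%` tail
#'   count attached as attribute `n_lt70` (also a column `n_lt70` repeated
#'   for convenience in exports).
#' @export
identity_distribution <- function(map, thresholds = c(100, 98, 96, 90, 80, 70)) {
  stopifnot(inherits(map, "ortholog_map"))
  if (nrow(map$bbh) == 0) abort("ortholog map has no BBH pairs")
  ids <- map$bbh$aa_identity
  out <- tibble(
    threshold = thresholds,
    n_ge = vapply(thresholds, function(t) sum(ids >= t), integer(1)),
    frac_ge = vapply(thresholds, function(t) mean(ids >= t), numeric(1)),
    n_total = length(ids)
  )
  attr(out, "n_lt70") <- sum(ids < 70)
  out
}
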