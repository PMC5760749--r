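#' Run the full two-genome comparison
#'
#' Orchestrates the whole pipeline: genome summaries, best-hit orthology
#' and classification, BBH identity distribution, synteny profile, calling
#' and accounting of gene-content difference regions, the modal codon
#' usage report with shuffled-pool nulls, and (optionally) fragment ANI.
#'
#' @param a,b `genome` objects (see [load_genome()] / [simulate_pair()]).
#' @param alignment_params See [default_alignment_params()].
#' @param region_params See [default_region_params()].
#' @param n_rounds Shuffling rounds for the codon-usage null.
#' @param seed Master seed; all randomness in the run derives from it.
#' @param skip_ani Skip the ANI block (it is the slowest stage on large
#'   genomes); no other block changes.
#' @return An object of class `comparison_report`: a named list of tibbles
#'   (`summary`, `ortholog_glance`, `identity_distribution`,
#'   `synteny_profile`, `regions`, `region_accounting`, `codon_report`,
#'   `ani`) plus the `ortholog_map` and provenance (`seed`, parameter
#'   lists).
#' @export
compare_genomes <- function(a, b,
                            alignment_params = default_alignment_params(),
                            region_params = default_region_params(),
                            n_rounds = 10L, seed = 1L, skip_ani = FALSE) {
  stopifnot(is_genome(a), is_genome(b))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  summary_tbl <- stage("summarize", bind_rows(summarize_genome(a), summarize_genome(b)))
  map <- stage("orthology", ortholog_map(a, b, alignment_params))
  iddist <- stage("identity_distribution", identity_distribution(map))
  profile <- stage("synteny", build_profile(map))
  regions <- stage("regions", call_regions(map, region_params))
  acct <- stage("region_accounting", region_accounting(regions, map))
  codon <- stage("codon_usage",
                 hgt_report(a, b, regions, n_rounds = n_rounds, seed = seed))
  ani <- if (skip_ani) NULL else stage("ani", compute_ani(a, b))

  structure(
    list(summary = summary_tbl,
         ortholog_glance = glance(map),
         identity_distribution = iddist,
         synteny_profile = as_tibble(profile),
         regions = as_tibble(regions),
         region_accounting = acct,
         codon_report = codon,
         ani = if (is.null(ani)) NULL else as_tibble(ani),
         map = map,
         genome_id_a = a$genome_id, genome_id_b = b$genome_id,
         seed = seed, n_rounds = n_rounds,
         alignment_params = map$params, region_params = region_params),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$genome_id_a, " vs ", x$genome_id_b, "\n", sep = "")
  og <- x$ortholog_glance
  cat("  BBH pairs: ", og$n_bbh, "; unique: ", og$n_unique_a, " (a), ",
      og$n_unique_b, " (b)\n", sep = "")
  cat("  difference regions: ", nrow(x$regions), "\n", sep = "")
  if (!is.null(x$ani)) {
    cat(sprintf("  ANI: %.1f%%\n", x$ani$ani_percent[x$ani$direction == "mean"]))
  }
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Serialises every block of a [compare_genomes()] report into a directory
#' of machine-readable files: `report.json` (all tables plus provenance),
#' per-table TSVs (`summary.tsv`, `identity_distribution.tsv`,
#' `synteny_points.tsv`, `regions.tsv`, `codon_distances.tsv`,
#' `ani.tsv`), and `regions.bed` per genome when the genomes are given.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @param a,b Optional `genome` objects for BED export of the regions.
#' @return Invisibly, `dir`.
#' @export
write_comparison_report <- function(report, dir, a = NULL, b = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    if (!is.null(tbl)) readr::write_tsv(tbl, file.path(dir, name))
  }
  wr(report$summary, "summary.tsv")
  wr(tidy(report$map), "gene_classification.tsv")
  wr(report$identity_distribution, "identity_distribution.tsv")
  wr(report$synteny_profile, "synteny_points.tsv")
  wr(report$regions, "regions.tsv")
  wr(report$region_accounting, "region_accounting.tsv")
  wr(report$codon_report, "codon_distances.tsv")
  wr(report$ani, "ani.tsv")
  if (!is.null(a) && nrow(report$regions) > 0) {
    wr(regions_to_bed(report$regions, a, "a"), "regions_a.bed")
  }
  if (!is.null(b) && nrow(report$regions) > 0) {
    wr(regions_to_bed(report$regions, b, "b"), "regions_b.bed")
  }
  payload <- list(
    genome_a = report$genome_id_a, genome_b = report$genome_id_b,
    seed = report$seed, n_rounds = report$n_rounds,
    alignment_params = report$alignment_params,
    region_params = report$region_params,
    summary = report$summary,
    ortholog_glance = report$ortholog_glance,
    identity_distribution = report$identity_distribution,
    regions = report$regions,
    region_accounting = report$region_accounting,
    codon_report = report$codon_report,
    ani = report$ani
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Synteny plot of BBH anchors
#'
#' Gene-number-vs-gene-number scatter of the bidirectional best hits, with
#' points coloured by amino-acid identity band; regions of gene-content
#' difference appear as gaps in the anchor diagonal.
#'
#' @param profile A `synteny_profile` from [build_profile()].
#' @return A ggplot object.
#' @export
plot_synteny <- function(profile) {
  df <- as_tibble(profile) |>
    mutate(identity_band = cut(.data$aa_identity,
                               breaks = c(0, 70, 96, 98, 100.001),
                               labels = c("<70%", "70-96%", "96-98%", ">=98%"),
                               right = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a_ordinal, y = .data$b_ordinal,
                                   colour = .data$identity_band)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "gene number, genome A", y = "gene number, genome B",
                  colour = "amino-acid identity") +
    ggplot2::theme_minimal()
}

#' Identity distribution plot of BBH pairs
#'
#' BBH amino-acid identity against position, with horizontal guides at
#' 96, 98 and 100 percent.
#'
#' @param map An `ortholog_map`.
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(map) {
  stopifnot(inherits(map, "ortholog_map"))
  ggplot2::ggplot(map$bbh, ggplot2::aes(x = .data$b_ordinal, y = .data$aa_identity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(96, 98, 100), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "gene number, genome B", y = "amino-acid identity (%)") +
    ggplot2::theme_minimal()
}
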