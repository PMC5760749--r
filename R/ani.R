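# Fragment-based average nucleotide identity.
#
# Goris-style convention: the query sequence is cut into consecutive
# 1,020-bp fragments (a trailing short fragment is discarded); each
# fragment is aligned to its best local match in the other genome, seeded
# by shared 15-mers and refined by local alignment within the seeded
# window; fragments with >= 30% identity over >= 70% of their length are
# retained, and ANI is the mean identity of retained fragments. Both
# directions are computed and the mean reported.

#' Compute average nucleotide identity between two genomes
#'
#' @param a,b `genome` objects (or plain nucleotide strings) whose
#'   sequences are at least `fragment_bp` long.
#' @param fragment_bp Fragment size in bp (default 1020).
#' @param min_identity Minimum fractional identity for a fragment to be
#'   retained (default 0.3).
#' @param min_coverage Minimum fraction of the fragment that must align
#'   (default 0.7).
#' @param k Seed k-mer size for locating each fragment (default 15).
#' @return A tibble of class `ani_result` with one row per direction plus
#'   the mean: `direction`, `ani_percent`, `n_fragments_total`,
#'   `n_fragments_retained`, `retained_fraction`, `fragment_bp`.
#' @export
compute_ani <- function(a, b, fragment_bp = 1020L, min_identity = 0.3,
                        min_coverage = 0.7, k = 15L) {
  seq_a <- if (is_genome(a)) a$sequence else toupper(a)
  seq_b <- if (is_genome(b)) b$sequence else toupper(b)
  if (nchar(seq_a) < fragment_bp || nchar(seq_b) < fragment_bp) {
    abort(paste0("both sequences must be at least fragment_bp (", fragment_bp, ") long"))
  }
  fwd <- ani_one_direction(seq_a, seq_b, fragment_bp, min_identity, min_coverage, k)
  rev <- ani_one_direction(seq_b, seq_a, fragment_bp, min_identity, min_coverage, k)
  out <- bind_rows(
    fwd |> mutate(direction = "a_vs_b"),
    rev |> mutate(direction = "b_vs_a"),
    tibble(direction = "mean",
           ani_percent = mean(c(fwd$ani_percent, rev$ani_percent)),
           n_fragments_total = fwd$n_fragments_total + rev$n_fragments_total,
           n_fragments_retained = fwd$n_fragments_retained + rev$n_fragments_retained,
           retained_fraction = (fwd$n_fragments_retained + rev$n_fragments_retained) /
             (fwd$n_fragments_total + rev$n_fragments_total))
  ) |>
    mutate(fragment_bp = fragment_bp) |>
    select("direction", dplyr::everything())
  structure(out, class = c("ani_result", class(out)))
}

ani_one_direction <- function(query, subject, fragment_bp, min_identity,
                              min_coverage, k) {
  qlen <- nchar(query)
  n_frag <- qlen %/% fragment_bp   # trailing short fragment discarded
  starts <- (seq_len(n_frag) - 1L) * fragment_bp + 1L
  frags <- substring(query, starts, starts + fragment_bp - 1L)

  # one seed table over all fragments, one join per strand
  seed_at <- seq(1L, fragment_bp - k + 1L, by = k)
  seeds <- tidyr::expand_grid(frag = seq_len(n_frag), qpos = seed_at) |>
    mutate(kmer = substring(frags[.data$frag], .data$qpos, .data$qpos + k - 1L))

  windows <- bind_rows(
    seed_windows(seeds, kmer_positions(subject, k), "fwd"),
    seed_windows(seeds, kmer_positions(reverse_complement(subject), k), "rev")
  )
  if (nrow(windows) > 0) {
    windows <- windows |>
      group_by(.data$frag) |>
      slice(which.max(.data$votes)) |>
      ungroup()
  }

  subj_rev <- reverse_complement(subject)
  identities <- rep(NA_real_, n_frag)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    subj <- if (w$strand == "rev") subj_rev else subject
    st <- ani_align_fragment(frags[w$frag], subj, w$diag, fragment_bp)
    if (!is.null(st) && st$coverage >= min_coverage && st$identity >= min_identity) {
      identities[w$frag] <- st$identity
    }
  }

  retained <- identities[!is.na(identities)]
  tibble(
    ani_percent = if (length(retained) > 0) 100 * mean(retained) else NA_real_,
    n_fragments_total = n_frag,
    n_fragments_retained = length(retained),
    retained_fraction = length(retained) / n_frag
  )
}

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(tibble(kmer = character(), pos = integer()))
  pos <- seq_len(n - k + 1L)
  tibble(kmer = substring(seq, pos, pos + k - 1L), pos = pos)
}

# Dominant seed diagonal per fragment on one subject strand; diagonals are
# binned to absorb small indels.
seed_windows <- function(seeds, idx, strand) {
  hits <- inner_join(seeds, idx, by = "kmer", relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(frag = integer(), diag = numeric(), votes = integer(),
                  strand = character()))
  }
  hits |>
    mutate(bin = round((.data$pos - .data$qpos) / 50)) |>
    dplyr::count(.data$frag, .data$bin) |>
    group_by(.data$frag) |>
    slice(which.max(.data$n)) |>
    ungroup() |>
    mutate(diag = .data$bin * 50, votes = .data$n, strand = strand) |>
    select("frag", "diag", "votes", "strand")
}

# Local alignment of a fragment against the seeded subject window.
ani_align_fragment <- function(frag, subj, diag, fragment_bp) {
  fl <- nchar(frag)
  margin <- 60L
  from <- max(1L, diag + 1L - margin)
  to <- min(nchar(subj), diag + fl + margin)
  if (to <= from) return(NULL)
  window <- substr(subj, from, to)
  paln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag), Biostrings::DNAString(window),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 3, gapExtension = 1
  )
  av <- strsplit(as.character(Biostrings::pattern(paln)), "")[[1]]
  bv <- strsplit(as.character(Biostrings::subject(paln)), "")[[1]]
  n_cols <- length(av)
  if (n_cols == 0) return(NULL)
  ident <- sum(av == bv & av != "-")
  aligned_q <- sum(av != "-")
  list(identity = ident / n_cols, coverage = aligned_q / fl)
}

#' @method glance ani_result
#' @export
glance.ani_result <- function(x, ...) {
  x |> filter(.data$direction == "mean") |> as_tibble()
}
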