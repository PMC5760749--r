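# Synteny profiling over BBH anchors and calling of contiguous regions of
# gene-content difference.
#
# The region caller formalizes what is usually read off a synteny plot by
# eye: a region is a run of "different" genes (unique or unidirectional),
# allowing short embedded runs of BBH anchors provided those anchors are
# themselves low-identity (< `low_identity`) or locally out of order. A
# conserved high-identity anchor, or too long a run of embedded anchors,
# terminates the region. Reported boundaries are the innermost flanking
# conserved anchors.

#' Default region-caller parameters
#'
#' @return A list: `min_nonbbh_run` (a region must contain a run of at
#'   least this many consecutive non-BBH genes, default 5),
#'   `max_bbh_interruptions` (longest tolerated run of consecutive embedded
#'   interrupting BBH anchors, default 3), `min_region_genes` (minimum
#'   total genes per region, default 20), `low_identity` (percent identity
#'   below which an embedded BBH counts as interrupting, default 70),
#'   `order_tolerance` (ordinal deviation from local collinearity beyond
#'   which an anchor counts as locally unordered, default 10).
#' @export
default_region_params <- function() {
  list(min_nonbbh_run = 5L, max_bbh_interruptions = 3L,
       min_region_genes = 20L, low_identity = 70, order_tolerance = 10)
}

#' Build a synteny profile from an ortholog map
#'
#' Orders the BBH anchors along genome `a` and flags runs of anchors that
#' break collinearity: inversions (runs of strictly decreasing counterpart
#' ordinals) and translocations (runs displaced from the local collinear
#' trend by more than a gap tolerance).
#'
#' @param map An `ortholog_map` with at least 2 BBH pairs.
#' @param min_run Minimum anchors for an inversion/translocation run
#'   (default 3).
#' @param gap_tolerance Ordinal displacement tolerated before an anchor is
#'   called translocated (default 20).
#' @return An object of class `synteny_profile`: tibble of anchors
#'   (`a_ordinal`, `b_ordinal`, `aa_identity`, `inverted`, `translocated`)
#'   with run counts in attributes `n_inversions`, `n_translocations`.
#' @export
build_profile <- function(map, min_run = 3L, gap_tolerance = 20) {
  stopifnot(inherits(map, "ortholog_map"))
  if (nrow(map$bbh) < 2) abort("need at least 2 BBH anchors to build a profile")
  anchors <- map$bbh |> arrange(.data$a_ordinal)
  b <- anchors$b_ordinal
  n <- length(b)

  # inversion: maximal runs of strictly decreasing counterpart ordinals
  dec <- diff(b) < 0
  inv <- rep(FALSE, n)
  r <- rle(dec)
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= (min_run - 1L)) {
      inv[pos[j]:(pos[j] + r$lengths[j])] <- TRUE
    }
  }

  # translocation: displacement from the median collinear offset
  offset <- stats::median(b - anchors$a_ordinal)
  displaced <- abs(b - anchors$a_ordinal - offset) > gap_tolerance & !inv
  tra <- rep(FALSE, n)
  r2 <- rle(displaced)
  pos2 <- cumsum(c(1, r2$lengths))
  for (j in seq_along(r2$values)) {
    if (r2$values[j] && r2$lengths[j] >= min_run) {
      tra[pos2[j]:(pos2[j] + r2$lengths[j] - 1L)] <- TRUE
    }
  }

  out <- anchors |>
    select("a_ordinal", "b_ordinal", "a_locus", "b_locus", "aa_identity") |>
    mutate(inverted = inv, translocated = tra)
  n_inv <- sum(rle(inv)$values)
  n_tra <- sum(rle(tra)$values)
  structure(out, class = c("synteny_profile", class(out)),
            n_inversions = n_inv, n_translocations = n_tra)
}

#' @method glance synteny_profile
#' @export
glance.synteny_profile <- function(x, ...) {
  tibble(n_anchors = nrow(x),
         n_inversions = attr(x, "n_inversions"),
         n_translocations = attr(x, "n_translocations"))
}

# Per-CDS status on one side: "diff" (unique or unidirectional),
# "int" (BBH that is low-identity or locally unordered), "cons" otherwise.
side_status <- function(map, side, params) {
  cls <- tidy(map) |> filter(.data$genome == side) |> arrange(.data$ordinal)
  status <- ifelse(cls$class %in% c("unique", "unidirectional"), "diff", "cons")
  is_bbh <- cls$class == "bbh"
  low_id <- is_bbh & cls$aa_identity < params$low_identity

  # local collinearity from high-identity anchors only
  hi <- which(is_bbh & !low_id)
  unordered <- rep(FALSE, nrow(cls))
  if (length(hi) >= 2) {
    expected <- stats::approx(x = cls$ordinal[hi], y = cls$counterpart_ordinal[hi],
                              xout = cls$ordinal, rule = 2)$y
    unordered <- is_bbh &
      abs(cls$counterpart_ordinal - expected) > params$order_tolerance
  }
  status[is_bbh & (low_id | unordered)] <- "int"
  cls$status <- status
  cls
}

# Scan one side's status sequence for candidate regions.
scan_regions <- function(cls, params) {
  st <- cls$status
  n <- length(st)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (st[i] != "diff") { i <- i + 1L; next }
    first <- i
    last <- i
    j <- i + 1L
    int_run <- 0L
    while (j <= n) {
      if (st[j] == "diff") {
        last <- j
        int_run <- 0L
      } else if (st[j] == "int") {
        int_run <- int_run + 1L
        if (int_run > params$max_bbh_interruptions) break
      } else break
      j <- j + 1L
    }
    span <- st[first:last]
    # the "run" of non-BBH genes is counted across the tolerated embedded
    # interruptions, so interleaved low-identity anchors do not reset it
    n_diff <- sum(span == "diff")
    if (n_diff >= params$min_nonbbh_run &&
        (last - first + 1L) >= params$min_region_genes) {
      regions[[length(regions) + 1]] <- c(first = first, last = last)
    }
    i <- j
  }
  regions
}

#' Call regions of gene-content difference
#'
#' Detects maximal contiguous chromosomal intervals in which orthologous
#' correspondence breaks down: runs of unique/unidirectional genes, allowing
#' embedded low-identity or locally unordered BBH anchors (at most
#' `max_bbh_interruptions` in a row). Regions are called from both genomes
#' and paired through their flanking conserved anchors.
#'
#' @param map An `ortholog_map`.
#' @param params See [default_region_params()].
#' @return A tibble of class `difference_regions`, one row per region:
#'   per-genome ordinal intervals (`a_first`, `a_last`, `b_first`,
#'   `b_last`, inclusive), bounding anchor loci, and per-genome gene
#'   accounting (`n_genes_*`, `n_unique_*`, `n_unidirectional_*`,
#'   `n_bbh_*`). Zero rows when the genomes are collinear.
#' @export
call_regions <- function(map, params = default_region_params()) {
  stopifnot(inherits(map, "ortholog_map"))
  params <- utils::modifyList(default_region_params(), params)

  cls_a <- side_status(map, "a", params)
  cls_b <- side_status(map, "b", params)

  build_side <- function(cls, other_cls, side) {
    found <- scan_regions(cls, params)
    purrr::map(found, function(fr) {
      first_ord <- cls$ordinal[fr["first"]]
      last_ord <- cls$ordinal[fr["last"]]
      # counterpart-interval mapping uses the nearest flanking BBH anchor of
      # any class: even a low-identity anchor maps coordinates, and using it
      # keeps regions separated by long interrupting runs from merging
      cons_idx <- which(cls$class == "bbh")
      left <- cons_idx[cons_idx < fr["first"]]
      right <- cons_idx[cons_idx > fr["last"]]
      left <- if (length(left) > 0) max(left) else NA_integer_
      right <- if (length(right) > 0) min(right) else NA_integer_
      cp_left <- if (!is.na(left)) cls$counterpart_ordinal[left] else NA_integer_
      cp_right <- if (!is.na(right)) cls$counterpart_ordinal[right] else NA_integer_
      other_interval <- sort(c(cp_left, cp_right))
      list(side = side, first = first_ord, last = last_ord,
           anchor_left = if (!is.na(left)) cls$locus_tag[left] else NA_character_,
           anchor_right = if (!is.na(right)) cls$locus_tag[right] else NA_character_,
           other_first = other_interval[1] + 1L, other_last = other_interval[2] - 1L)
    })
  }

  ra <- build_side(cls_a, cls_b, "a")
  rb <- build_side(cls_b, cls_a, "b")

  # express every call as an a-side interval, then merge overlapping calls
  as_a <- c(
    purrr::map(ra, function(r) c(a_first = r$first, a_last = r$last,
                                 b_first = r$other_first, b_last = r$other_last)),
    purrr::map(rb, function(r) c(a_first = r$other_first, a_last = r$other_last,
                                 b_first = r$first, b_last = r$last))
  )
  if (length(as_a) == 0) {
    return(empty_regions())
  }
  df <- bind_rows(purrr::map(as_a, ~as_tibble(as.list(.x)))) |>
    filter(!is.na(.data$a_first), !is.na(.data$a_last)) |>
    arrange(.data$a_first)
  # merge calls whose a-intervals overlap (the same region seen from both sides)
  merged <- list()
  for (i in seq_len(nrow(df))) {
    cur <- df[i, ]
    if (length(merged) > 0) {
      prev <- merged[[length(merged)]]
      if (cur$a_first <= prev$a_last + 1L) {
        prev$a_first <- min(prev$a_first, cur$a_first)
        prev$a_last <- max(prev$a_last, cur$a_last)
        prev$b_first <- min(prev$b_first, cur$b_first, na.rm = TRUE)
        prev$b_last <- max(prev$b_last, cur$b_last, na.rm = TRUE)
        merged[[length(merged)]] <- prev
        next
      }
    }
    merged[[length(merged) + 1]] <- cur
  }
  out <- bind_rows(merged) |>
    mutate(region_id = paste0("R", row_number()), .before = 1)

  # accounting + anchors from the a-side classification
  acct <- function(cls, first, last, suffix) {
    inside <- cls |> filter(.data$ordinal >= first, .data$ordinal <= last)
    tibble(
      "n_genes_{suffix}" := nrow(inside),
      "n_unique_{suffix}" := sum(inside$class == "unique"),
      "n_unidirectional_{suffix}" := sum(inside$class == "unidirectional"),
      "n_bbh_{suffix}" := sum(inside$class == "bbh")
    )
  }
  anchors <- function(cls, first, last) {
    cons <- cls |> filter(.data$status == "cons")
    left <- cons |> filter(.data$ordinal < first) |> slice(n())
    right <- cons |> filter(.data$ordinal > last) |> slice(1)
    tibble(anchor_left = if (nrow(left)) left$locus_tag else NA_character_,
           anchor_right = if (nrow(right)) right$locus_tag else NA_character_)
  }
  extra <- purrr::pmap(out, function(region_id, a_first, a_last, b_first, b_last) {
    dplyr::bind_cols(
      acct(cls_a, a_first, a_last, "a"),
      acct(cls_b, b_first, b_last, "b"),
      anchors(cls_a, a_first, a_last) |>
        rename(a_anchor_left = "anchor_left", a_anchor_right = "anchor_right"),
      anchors(cls_b, b_first, b_last) |>
        rename(b_anchor_left = "anchor_left", b_anchor_right = "anchor_right")
    )
  })
  out <- dplyr::bind_cols(out, bind_rows(extra))
  structure(out, class = c("difference_regions", class(out)))
}

empty_regions <- function() {
  out <- tibble(
    region_id = character(), a_first = integer(), a_last = integer(),
    b_first = integer(), b_last = integer(),
    n_genes_a = integer(), n_unique_a = integer(),
    n_unidirectional_a = integer(), n_bbh_a = integer(),
    n_genes_b = integer(), n_unique_b = integer(),
    n_unidirectional_b = integer(), n_bbh_b = integer(),
    a_anchor_left = character(), a_anchor_right = character(),
    b_anchor_left = character(), b_anchor_right = character()
  )
  structure(out, class = c("difference_regions", class(out)))
}

#' Account genes of called regions against the whole chromosome
#'
#' Per-genome gene accounting of the called regions plus the fraction of
#' all chromosome-wide unique genes captured by them (e.g. "the two regions
#' encompass 61 of the 147 unique genes").
#'
#' @param regions A `difference_regions` tibble from [call_regions()].
#' @param map The `ortholog_map` the regions were called from.
#' @return A tibble with one row per genome: `genome`, `n_regions`,
#'   `n_region_genes`, `n_region_unique`, `n_unique_total`,
#'   `capture_fraction`.
#' @export
region_accounting <- function(regions, map) {
  stopifnot(inherits(map, "ortholog_map"))
  one <- function(side) {
    cls <- tidy(map) |> filter(.data$genome == side)
    first <- regions[[paste0(side, "_first")]]
    last <- regions[[paste0(side, "_last")]]
    if (any(!is.na(first) & (first < 0 | last > max(cls$ordinal)))) {
      abort("region interval outside the genome")
    }
    in_region <- purrr::map2(first, last, ~cls$ordinal >= .x & cls$ordinal <= .y) |>
      purrr::reduce(`|`, .init = rep(FALSE, nrow(cls)))
    tibble(
      genome = side,
      n_regions = nrow(regions),
      n_region_genes = sum(in_region),
      n_region_unique = sum(in_region & cls$class == "unique"),
      n_unique_total = sum(cls$class == "unique"),
      capture_fraction = if (sum(cls$class == "unique") > 0) {
        sum(in_region & cls$class == "unique") / sum(cls$class == "unique")
      } else NA_real_
    )
  }
  bind_rows(one("a"), one("b"))
}

#' Export difference regions as BED intervals
#'
#' Converts the gene-ordinal intervals of called regions to nucleotide
#' coordinates (0-based half-open, per BED convention) on one genome.
#'
#' @param regions A `difference_regions` tibble.
#' @param genome The `genome` object of the requested side.
#' @param side `"a"` or `"b"`.
#' @return A tibble `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
regions_to_bed <- function(regions, genome, side = "a") {
  stopifnot(is_genome(genome))
  first <- regions[[paste0(side, "_first")]]
  last <- regions[[paste0(side, "_last")]]
  g <- genome$genes
  tibble(
    chrom = genome$genome_id,
    chromStart = g$start[match(first, g$ordinal)],
    chromEnd = g$end[match(last, g$ordinal)],
    name = regions$region_id
  )
}
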