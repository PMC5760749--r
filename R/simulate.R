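# Synthetic annotated genome pairs with known truth.
#
# The generator emulates the structure of a pair of very closely related
# bacterial chromosomes: a collinear ortholog backbone with a heavily
# right-skewed amino-acid identity distribution, plus contiguous planted
# regions whose genes carry a codon usage bias divergent from the backbone
# (the footprint of horizontal acquisition). Each simulated pair ships
# with a truth record (ortholog pairs with realized identity, planted
# intervals, per-gene bias labels) so every pipeline stage can be checked
# against ground truth.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# typical proteobacterial amino-acid composition (normalised below)
default_aa_freqs <- function() {
  f <- c(A = 0.088, R = 0.055, N = 0.040, D = 0.054, C = 0.012, Q = 0.039,
         E = 0.058, G = 0.074, H = 0.022, I = 0.059, L = 0.096, K = 0.044,
         M = 0.021, F = 0.039, P = 0.044, S = 0.058, T = 0.054, W = 0.014,
         Y = 0.032, V = 0.066)
  f / sum(f)
}

#' Default (backbone) codon usage bias
#'
#' Per-family codon frequency vectors with an AT-rich wobble preference
#' (third-position A/T codons weighted 3:1), consistent with a low-GC
#' chromosome.
#'
#' @return Named list: one frequency vector per multi-codon family.
#' @export
default_codon_bias <- function() {
  u <- codon_universe()
  purrr::map(u$families, function(cods) {
    w <- ifelse(substr(cods, 3, 3) %in% c("A", "T"), 3, 1)
    setNames(w / sum(w), cods)
  })
}

#' Shift a codon bias away from a reference by a fixed total variation
#'
#' For each codon family, moves probability mass toward one target codon
#' (the `rank`-th least-preferred under `bias`) so that the family's
#' total-variation distance from `bias` equals `tv` (clamped at the
#' maximum achievable). Used to construct donor biases for planted
#' regions; different `rank` values give donors that also differ from
#' each other.
#'
#' @param bias Family frequency list, e.g. [default_codon_bias()].
#' @param tv Target per-family total-variation distance in `[0, 1)`.
#' @param rank Which least-preferred codon to shift toward (1 = least).
#' @return A family frequency list.
#' @export
shifted_bias <- function(bias, tv, rank = 1L) {
  if (tv == 0) return(bias)
  purrr::map(bias, function(fr) {
    ord <- order(fr)
    k <- ord[min(rank, length(fr))]
    lambda <- min(1, tv / (1 - fr[k]))
    out <- (1 - lambda) * fr
    out[k] <- out[k] + lambda
    out
  })
}

#' Paper-like simulation configuration
#'
#' A configuration whose expected summary statistics echo the structure of
#' a real close strain pair at desk scale: ~300 collinear ortholog pairs
#' of which 86% exceed 98% amino-acid identity and 94% exceed 96%, plus
#' two planted regions of 53 and 48 genes whose codon usage is drawn from
#' donor biases at total-variation 0.4 from the backbone, with realistic
#' unique-gene fractions on both sides.
#'
#' @param seed Integer seed stored in the config; all randomness of
#'   [simulate_pair()] flows from it.
#' @param n_backbone_genes Number of backbone ortholog pairs (default 300;
#'   scaling up changes size only, not structure).
#' @return An object of class `sim_config` (a named list).
#' @export
default_pair_config <- function(seed = 1L, n_backbone_genes = 300L) {
  backbone <- default_codon_bias()
  cfg <- list(
    seed = as.integer(seed),
    n_backbone_genes = as.integer(n_backbone_genes),
    gene_length_mean = 200, gene_length_sd = 60, gene_length_min = 60,
    aa_freqs = default_aa_freqs(),
    backbone_codon_bias = backbone,
    # identity bands (percent) and mixture weights; right-skewed like the
    # observed BBH identity distribution
    identity_mixture = tibble(
      lower = c(98, 96, 90, 70, 40),
      upper = c(100, 98, 96, 90, 70),
      weight = c(0.86, 0.08, 0.04, 0.015, 0.005)
    ),
    synonymous_resample = 0.08,
    minus_strand_fraction = 0.3,
    planted_regions = list(
      list(name = "A", n_genes = 53L, n_unique_a = 29L, n_unique_b = 25L,
           donor_tv = 0.4, donor_rank = 1L, insert_after = 75L,
           homolog_identity = c(40, 65)),
      list(name = "B", n_genes = 48L, n_unique_a = 32L, n_unique_b = 56L,
           donor_tv = 0.4, donor_rank = 2L, insert_after = 180L,
           homolog_identity = c(40, 65))
    ),
    intergenic_mean = 120, intergenic_sd = 40, intergenic_min = 2,
    intergenic_divergence = 0.02,
    gc_target = NA_real_
  )
  cfg$gc_target <- expected_coding_gc(cfg$aa_freqs, backbone)
  structure(cfg, class = "sim_config")
}

# Analytic expectation of coding GC under an amino-acid composition and a
# codon bias (single-codon families included at their fixed codons).
expected_coding_gc <- function(aa_freqs, bias) {
  u <- codon_universe()
  gc11 <- Biostrings::getGeneticCode("11")
  total <- 0
  for (aa in names(aa_freqs)) {
    cods <- names(gc11)[gc11 == aa]
    fr <- if (aa %in% names(bias)) bias[[aa]][cods] else setNames(rep(1 / length(cods), length(cods)), cods)
    gc_c <- vapply(cods, function(cd) {
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3
    }, numeric(1))
    total <- total + aa_freqs[[aa]] * sum(fr * gc_c)
  }
  unname(total)
}

sample_protein <- function(len, aa_freqs) {
  c("M", sample(AA20, len - 1, replace = TRUE, prob = aa_freqs))
}

# codons for an amino-acid vector under a family bias (vectorised per
# family; single-codon amino acids get their fixed codon)
sample_codons <- function(aa_vec, bias) {
  gc11 <- codon_universe()$code
  out <- character(length(aa_vec))
  for (aa in unique(aa_vec)) {
    idx <- which(aa_vec == aa)
    if (aa %in% names(bias)) {
      fr <- bias[[aa]]
      out[idx] <- sample(names(fr), length(idx), replace = TRUE, prob = fr)
    } else {
      out[idx] <- names(gc11)[gc11 == aa][1]   # Met, Trp
    }
  }
  out
}

# substitute n_sub positions (never position 1) with different residues;
# replacement prefers biochemically similar residues (BLOSUM62 > 0)
substitute_residues <- function(aa_vec, n_sub) {
  if (n_sub == 0) return(aa_vec)
  bl <- blosum62()[AA20, AA20]
  pos <- sample(seq.int(2L, length(aa_vec)), n_sub)
  for (p in pos) {
    cur <- aa_vec[p]
    sims <- setdiff(AA20[bl[cur, ] > 0], cur)
    aa_vec[p] <- if (length(sims) > 0 && runif(1) < 0.7) {
      sample(sims, 1)
    } else {
      sample(setdiff(AA20, cur), 1)
    }
  }
  aa_vec
}

# interleave h homolog genes among u unique genes: unique genes at both
# ends, homologs distributed into the internal gaps (at most 2 per gap),
# so no homolog run exceeds 2. Deterministic.
interleave_block <- function(u, h) {
  if (u < 2 && h > 0) abort("planted block needs at least 2 unique genes to anchor its ends")
  if (h > 2 * (u - 1)) abort("too many homologs to interleave at run length <= 2")
  gaps <- rep(0L, u - 1)
  g <- 1L
  while (h > 0) {
    if (gaps[g] < 2L) { gaps[g] <- gaps[g] + 1L; h <- h - 1L }
    g <- g + 1L
    if (g > length(gaps)) g <- 1L
  }
  out <- character(0)
  for (i in seq_len(u - 1)) {
    out <- c(out, "unique", rep("homolog", gaps[i]))
  }
  c(out, "unique")
}

#' Simulate an annotated genome pair with known truth
#'
#' Generates two collinear annotated genomes from a shared ancestor: each
#' backbone gene pair is mutated to a drawn target amino-acid identity
#' (substitutions via a BLOSUM-informed kernel, synonymous positions
#' resampled from the backbone codon bias), and planted regions are
#' inserted as contiguous blocks of donor-biased genes, part unique to
#' each genome and part diverged low-identity homologs. Fully
#' deterministic given `config$seed`.
#'
#' @param config A `sim_config`, see [default_pair_config()].
#' @return A list `a`, `b` (two `genome` objects) and `truth` (list with
#'   tibbles `orthologs`, `regions`, `gene_bias`).
#' @export
simulate_pair <- function(config = default_pair_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  inserts <- purrr::map_int(cfg$planted_regions, "insert_after")
  if (any(duplicated(inserts)) || any(inserts > cfg$n_backbone_genes)) {
    abort("planted region insert positions must be distinct and inside the backbone")
  }
  if (length(inserts) > 1 && any(diff(sort(inserts)) == 0)) {
    abort("overlapping planted regions")
  }

  draw_len <- function(n) {
    pmax(cfg$gene_length_min,
         round(rnorm(n, cfg$gene_length_mean, cfg$gene_length_sd)))
  }
  mixture_identity <- function(n) {
    mix <- cfg$identity_mixture
    band <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    runif(n, mix$lower[band], mix$upper[band])
  }

  # ---- backbone gene pairs -------------------------------------------------
  nb <- cfg$n_backbone_genes
  lens <- draw_len(nb)
  targets <- mixture_identity(nb)
  backbone <- vector("list", nb)
  for (i in seq_len(nb)) {
    anc <- sample_protein(lens[i], cfg$aa_freqs)
    n_sub <- round((1 - targets[i] / 100) * lens[i])
    n_sub <- min(n_sub, lens[i] - 1L)
    aa_b <- substitute_residues(anc, n_sub)
    cod_a <- sample_codons(anc, cfg$backbone_codon_bias)
    cod_b <- cod_a
    changed <- which(aa_b != anc)
    if (length(changed) > 0) {
      cod_b[changed] <- sample_codons(aa_b[changed], cfg$backbone_codon_bias)
    }
    syn <- setdiff(which(runif(lens[i]) < cfg$synonymous_resample), changed)
    if (length(syn) > 0) {
      cod_b[syn] <- sample_codons(aa_b[syn], cfg$backbone_codon_bias)
    }
    backbone[[i]] <- list(
      cod_a = cod_a, cod_b = cod_b,
      realized_identity = 100 * (lens[i] - length(changed)) / lens[i]
    )
  }

  # ---- planted regions -----------------------------------------------------
  regions <- purrr::map(cfg$planted_regions, function(rg) {
    donor <- shifted_bias(cfg$backbone_codon_bias, rg$donor_tv, rg$donor_rank)
    n_hom <- rg$n_genes - rg$n_unique_a
    homologs <- purrr::map(seq_len(n_hom), function(i) {
      L <- draw_len(1)
      anc <- sample_protein(L, cfg$aa_freqs)
      t <- runif(1, rg$homolog_identity[1], rg$homolog_identity[2])
      n_sub <- min(round((1 - t / 100) * L), L - 1L)
      aa_b <- substitute_residues(anc, n_sub)
      list(cod_a = sample_codons(anc, donor),
           cod_b = sample_codons(aa_b, donor),
           realized_identity = 100 * sum(aa_b == anc) / L)
    })
    fresh <- function(n) {
      purrr::map(seq_len(n), function(i) {
        sample_codons(sample_protein(draw_len(1), cfg$aa_freqs), donor)
      })
    }
    list(name = rg$name, insert_after = rg$insert_after,
         donor_tv = rg$donor_tv, homologs = homologs,
         unique_a = fresh(rg$n_unique_a), unique_b = fresh(rg$n_unique_b),
         layout_a = interleave_block(rg$n_unique_a, n_hom),
         layout_b = interleave_block(rg$n_unique_b, n_hom))
  })

  # ---- lay out both genomes ------------------------------------------------
  # Each build entry carries its codons, preceding intergenic spacer and
  # strand. Orthologous genes keep the same strand on both genomes, and
  # backbone spacers descend from a shared ancestor with light divergence,
  # as expected for very close strains; region spacers are independent.
  draw_spacer <- function() {
    L <- max(cfg$intergenic_min,
             round(rnorm(1, cfg$intergenic_mean, cfg$intergenic_sd)))
    paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                 prob = c(cfg$gc_target / 2, cfg$gc_target / 2,
                          (1 - cfg$gc_target) / 2, (1 - cfg$gc_target) / 2)),
          collapse = "")
  }
  mutate_bases <- function(seq, rate) {
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < rate)
    for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  draw_strand <- function() if (runif(1) < cfg$minus_strand_fraction) "-" else "+"

  build <- list(a = list(), b = list())
  add_gene <- function(side, codons, label, pair_id, strand, spacer) {
    build[[side]][[length(build[[side]]) + 1]] <<-
      list(codons = codons, label = label, pair_id = pair_id,
           strand = strand, spacer = spacer)
  }
  region_marks <- list(a = list(), b = list())

  reg_by_pos <- setNames(regions, as.character(purrr::map_int(regions, "insert_after")))
  for (i in seq_len(nb)) {
    strand <- draw_strand()
    sp <- draw_spacer()
    add_gene("a", backbone[[i]]$cod_a, "backbone", paste0("bb", i), strand, sp)
    add_gene("b", backbone[[i]]$cod_b, "backbone", paste0("bb", i), strand,
             mutate_bases(sp, cfg$intergenic_divergence))
    rg <- reg_by_pos[[as.character(i)]]
    if (!is.null(rg)) {
      hom_strands <- vapply(seq_along(rg$homologs), function(x) draw_strand(),
                            character(1))
      for (side in c("a", "b")) {
        layout <- rg[[paste0("layout_", side)]]
        uniq <- rg[[paste0("unique_", side)]]
        first_idx <- length(build[[side]]) + 1L
        iu <- 0L; ih <- 0L
        for (slot in layout) {
          if (slot == "unique") {
            iu <- iu + 1L
            add_gene(side, uniq[[iu]], paste0("donor_", rg$name), NA_character_,
                     draw_strand(), draw_spacer())
          } else {
            ih <- ih + 1L
            add_gene(side, rg$homologs[[ih]][[paste0("cod_", side)]],
                     paste0("donor_", rg$name),
                     paste0("hom_", rg$name, "_", ih),
                     hom_strands[ih], draw_spacer())
          }
        }
        region_marks[[side]][[rg$name]] <-
          c(first = first_idx, last = length(build[[side]]))
      }
    }
  }
  final_spacer <- draw_spacer()
  final_spacers <- c(a = final_spacer,
                     b = mutate_bases(final_spacer, cfg$intergenic_divergence))

  # ---- emit sequences ------------------------------------------------------
  emit <- function(side, genome_id, tag_prefix) {
    genes <- build[[side]]
    n <- length(genes)
    seq_parts <- character(0)
    rows <- vector("list", n)
    pos <- 0L
    for (i in seq_len(n)) {
      seq_parts <- c(seq_parts, genes[[i]]$spacer)
      pos <- pos + nchar(genes[[i]]$spacer)
      nt <- paste0(paste(genes[[i]]$codons, collapse = ""), "TAA")
      nt_genomic <- if (genes[[i]]$strand == "-") reverse_complement(nt) else nt
      seq_parts <- c(seq_parts, nt_genomic)
      rows[[i]] <- tibble(
        locus_tag = sprintf("%s_%04d", tag_prefix, i),
        start = pos, end = pos + nchar(nt),
        strand = genes[[i]]$strand, feature_kind = "CDS",
        product = if (genes[[i]]$label == "backbone") "conserved protein"
                  else "hypothetical protein",
        label = genes[[i]]$label, pair_id = genes[[i]]$pair_id
      )
      pos <- pos + nchar(nt)
    }
    seq_parts <- c(seq_parts, final_spacers[[side]])
    meta <- bind_rows(rows)
    genome <- new_genome(genome_id, paste(seq_parts, collapse = ""),
                         meta |> select(-"label", -"pair_id"),
                         source_format = "simulated")
    list(genome = genome, meta = meta)
  }

  ea <- emit("a", "simA", "A")
  eb <- emit("b", "simB", "B")

  # ---- truth record --------------------------------------------------------
  pair_tbl <- function(meta, side) {
    meta |>
      mutate(ordinal = row_number() - 1L) |>
      select("pair_id", "label", locus = "locus_tag", ordinal)
  }
  ta <- pair_tbl(ea$meta, "a")
  tb <- pair_tbl(eb$meta, "b")
  realized <- c(
    setNames(purrr::map_dbl(backbone, "realized_identity"),
             paste0("bb", seq_len(nb))),
    unlist(purrr::map(regions, function(rg) {
      setNames(purrr::map_dbl(rg$homologs, "realized_identity"),
               paste0("hom_", rg$name, "_", seq_along(rg$homologs),
                      recycle0 = TRUE))
    }))
  )
  orthologs <- inner_join(
    ta |> filter(!is.na(.data$pair_id)) |>
      select("pair_id", a_locus = "locus", a_ordinal = "ordinal"),
    tb |> filter(!is.na(.data$pair_id)) |>
      select("pair_id", b_locus = "locus", b_ordinal = "ordinal"),
    by = "pair_id"
  ) |>
    mutate(realized_identity = unname(realized[.data$pair_id]),
           type = ifelse(grepl("^bb", .data$pair_id), "backbone", "homolog"))

  region_truth <- purrr::map(regions, function(rg) {
    ma <- region_marks$a[[rg$name]]
    mb <- region_marks$b[[rg$name]]
    ga <- ea$genome$genes; gb <- eb$genome$genes
    tibble(
      region = rg$name, donor_tv = rg$donor_tv,
      a_first = ma[["first"]] - 1L, a_last = ma[["last"]] - 1L,
      b_first = mb[["first"]] - 1L, b_last = mb[["last"]] - 1L,
      n_genes_a = ma[["last"]] - ma[["first"]] + 1L,
      n_genes_b = mb[["last"]] - mb[["first"]] + 1L,
      n_unique_a = sum(is.na(ta$pair_id[ma[["first"]]:ma[["last"]]])),
      n_unique_b = sum(is.na(tb$pair_id[mb[["first"]]:mb[["last"]]])),
      a_start_bp = ga$start[ma[["first"]]], a_end_bp = ga$end[ma[["last"]]],
      b_start_bp = gb$start[mb[["first"]]], b_end_bp = gb$end[mb[["last"]]]
    )
  }) |> bind_rows()

  gene_bias <- bind_rows(
    ta |> mutate(genome = "a"),
    tb |> mutate(genome = "b")
  ) |> select("genome", "locus", bias_label = "label")

  list(a = ea$genome, b = eb$genome,
       truth = list(orthologs = orthologs, regions = region_truth,
                    gene_bias = gene_bias),
       config = config)
}

#' Simulate codon-count gene sets directly
#'
#' Draws two gene sets of codon counts, one from each of two codon biases,
#' without building genome sequences. Used for calibration and power
#' studies of the shuffled-pool test.
#'
#' @param n1,n2 Genes per set.
#' @param bias1,bias2 Family frequency lists (default: the backbone bias).
#' @param length_mean,length_sd Gene length distribution in codons.
#' @param aa_freqs Amino-acid composition.
#' @param seed Integer seed.
#' @return List of two codon-count tibbles `set1`, `set2`.
#' @export
simulate_codon_sets <- function(n1, n2, bias1 = default_codon_bias(),
                                bias2 = default_codon_bias(),
                                length_mean = 200, length_sd = 60,
                                aa_freqs = default_aa_freqs(), seed = 1L) {
  set.seed(seed)
  u <- codon_universe()
  one_set <- function(n, bias, prefix) {
    rows <- purrr::map(seq_len(n), function(i) {
      L <- max(60, round(rnorm(1, length_mean, length_sd)))
      aa <- sample(AA20, L, replace = TRUE, prob = aa_freqs)
      cods <- sample_codons(aa, bias)
      counts <- setNames(integer(64), u$codons)
      tb <- table(factor(cods, levels = u$codons))
      counts[] <- as.integer(tb)
      dplyr::bind_cols(tibble(gene_id = sprintf("%s%04d", prefix, i)),
                       as_tibble(as.list(counts)))
    })
    out <- bind_rows(rows)
    out$n_codons <- as.integer(rowSums(as.matrix(out[, u$codons])))
    out
  }
  list(set1 = one_set(n1, bias1, "s1_"), set2 = one_set(n2, bias2, "s2_"))
}
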