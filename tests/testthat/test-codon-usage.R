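test_that("codon counting matches examples and a sliding-index oracle", {
  c1 <- count_codons("ATGAAAAAATAA", exclude_termini = FALSE)
  expect_equal(c1[["ATG"]], 1L)
  expect_equal(c1[["AAA"]], 2L)
  expect_equal(c1[["TAA"]], 1L)
  expect_equal(sum(c1), 4L)

  c2 <- count_codons("ATGAAAAAATAA", exclude_termini = TRUE)
  expect_equal(c2[["AAA"]], 2L)
  expect_equal(sum(c2), 2L)

  # 300-codon random CDS against an index-walk oracle
  set.seed(41)
  nt <- backtranslate(random_protein(300))
  got <- count_codons(nt, exclude_termini = FALSE)
  oracle <- integer(0)
  for (i in seq(1, nchar(nt) - 2, by = 3)) {
    cod <- substr(nt, i, i + 2)
    oracle[cod] <- (if (is.na(oracle[cod])) 0L else oracle[cod]) + 1L
  }
  for (cod in names(oracle)) expect_equal(got[[cod]], oracle[[cod]])
  expect_equal(sum(got), sum(oracle))

  # codons containing ambiguity codes are skipped
  expect_equal(sum(count_codons("ATGANAAAATAA", exclude_termini = FALSE)), 3L)
  expect_error(count_codons("ATGAA"), "divisible")
})

test_that("codon_counts works per genome subset and rejects empty selections", {
  sim <- simulate_pair(small_sim_config(seed = 2, n_backbone = 10, regions = list()))
  cc <- codon_counts(sim$a)
  expect_equal(nrow(cc), 10)
  expect_equal(cc$n_codons, as.integer(rowSums(as.matrix(cc[, 2:65]))))
  expect_error(codon_counts(sim$a, ordinals = 9999), "no complete CDS")
})

test_that("a single gene is its own modal codon usage (trivial fixed point)", {
  sets <- simulate_codon_sets(1, 1, seed = 6)
  m <- compute_mode(sets$set1)
  expect_true(m$converged)
  expect_equal(m$conforming_genes, sets$set1$gene_id)
  u <- genomepair:::codon_universe()
  cm <- genomepair:::counts_matrix(sets$set1)
  for (f in names(u$families)) {
    tot <- colSums(cm[, u$families[[f]], drop = FALSE])
    if (sum(tot) > 0) {
      expect_equal(m$freqs$freq[m$freqs$family == f], unname(tot / sum(tot)))
    }
  }
})

test_that("compute_mode is a fixed point and invariant to order and duplication", {
  sets <- simulate_codon_sets(80, 1, seed = 9)
  m <- compute_mode(sets$set1)
  expect_true(m$converged)
  # family frequencies sum to one
  sums <- tapply(m$freqs$freq, m$freqs$family, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # fixed point: re-pooling over the conforming genes reproduces the mode
  sub <- sets$set1[sets$set1$gene_id %in% m$conforming_genes, ]
  expect_equal(compute_mode(sub)$freqs$freq, m$freqs$freq)
  # input order invariance
  shuf <- sets$set1[sample.int(nrow(sets$set1)), ]
  expect_equal(compute_mode(shuf)$freqs$freq, m$freqs$freq)
  # duplicating the whole input set changes nothing
  dup <- dplyr::bind_rows(sets$set1, sets$set1)
  expect_equal(compute_mode(dup)$freqs$freq, m$freqs$freq)
})

test_that("the mode of a homogeneous 200-gene set recovers the generating bias", {
  sets <- simulate_codon_sets(200, 1, seed = 3)
  m <- compute_mode(sets$set1)
  bias <- default_codon_bias()
  aaf <- genomepair:::default_aa_freqs()
  w <- aaf[names(bias)] / sum(aaf[names(bias)])
  wtv <- sum(w * vapply(names(bias), function(f) {
    genomepair:::tv_distance(m$freqs$freq[m$freqs$family == f], unname(bias[[f]]))
  }, numeric(1)))
  expect_lt(wtv, 0.02)
  # most genes of a homogeneous set conform at p > 0.1
  expect_gt(length(m$conforming_genes) / 200, 0.8)
})

test_that("an 80:20 mixture converges to the majority bias", {
  bias <- default_codon_bias()
  divergent <- shifted_bias(bias, 0.5)
  mix <- simulate_codon_sets(160, 40, bias1 = bias, bias2 = divergent, seed = 4)
  m <- compute_mode(dplyr::bind_rows(mix$set1, mix$set2))
  expect_gte(mean(mix$set1$gene_id %in% m$conforming_genes), 0.9)
  expect_lt(mean(mix$set2$gene_id %in% m$conforming_genes), 0.1)
  aaf <- genomepair:::default_aa_freqs()
  w <- aaf[names(bias)] / sum(aaf[names(bias)])
  wtv <- sum(w * vapply(names(bias), function(f) {
    genomepair:::tv_distance(m$freqs$freq[m$freqs$family == f], unname(bias[[f]]))
  }, numeric(1)))
  expect_lt(wtv, 0.03)
})

test_that("mode distance is a pseudometric and matches a hand computation", {
  sets <- simulate_codon_sets(30, 30, seed = 10)
  m1 <- compute_mode(sets$set1)
  m2 <- compute_mode(sets$set2)
  expect_equal(mode_distance(m1, m1), 0)
  expect_gte(mode_distance(m1, m2), 0)
  expect_equal(mode_distance(m1, m2), mode_distance(m2, m1))

  # two-family toy with hand-set frequencies and weights:
  # w = ((0.75,0.25) + (0.25,0.75))/2 = (0.5, 0.5); TV_K = 0.3, TV_N = 0.4
  mk_mode <- function(fK, fN, totK, totN) {
    structure(list(
      freqs = tibble::tibble(family = c("K", "K", "N", "N"),
                             codon = c("AAA", "AAG", "AAT", "AAC"),
                             freq = c(fK, fN)),
      family_totals = c(K = totK, N = totN),
      conforming_genes = "g", n_genes_input = 1L,
      n_iterations = 1L, converged = TRUE), class = "codon_mode")
  }
  t1 <- mk_mode(c(0.7, 0.3), c(0.5, 0.5), 300, 100)
  t2 <- mk_mode(c(0.4, 0.6), c(0.9, 0.1), 100, 300)
  expect_equal(mode_distance(t1, t2), 0.5 * 0.3 + 0.5 * 0.4, tolerance = 1e-12)
  expect_error(mode_distance(t1, m1), "different codon families")
})

test_that("the shuffled-pool null is reproducible and zero for identical sets", {
  sets <- simulate_codon_sets(25, 25, seed = 15)
  r0 <- shuffled_null(sets$set1, sets$set1, n_rounds = 5, seed = 2)
  expect_equal(r0$observed_distance, 0)

  r1 <- shuffled_null(sets$set1, sets$set2, n_rounds = 10, seed = 7)
  r2 <- shuffled_null(sets$set1, sets$set2, n_rounds = 10, seed = 7)
  expect_identical(r1$per_round_distances, r2$per_round_distances)
  expect_identical(r1$observed_distance, r2$observed_distance)
  r3 <- shuffled_null(sets$set1, sets$set2, n_rounds = 10, seed = 8)
  expect_false(identical(r3$per_round_distances, r1$per_round_distances))
  expect_equal(r1$n_rounds, length(r1$per_round_distances))
  expect_gte(r1$null_sd, 0)
  expect_error(shuffled_null(sets$set1[0, ], sets$set2[0, ]), "two genes")
})

test_that("a planted divergent gene set is detected against the shuffled null", {
  bias <- default_codon_bias()
  donor <- shifted_bias(bias, 0.4)
  cs <- simulate_codon_sets(40, 200, bias1 = donor, bias2 = bias, seed = 31)
  r <- shuffled_null(cs$set1, cs$set2, n_rounds = 10, seed = 31)
  expect_gt(r$observed_distance, r$null_mean + 3 * r$null_sd)
})

test_that("hgt_report mirrors the expected comparison rows and flags empty sets", {
  sim <- simulate_pair(small_sim_config(seed = 25))
  map <- ortholog_map(sim$a, sim$b)
  regs <- call_regions(map)
  rep <- hgt_report(sim$a, sim$b, regs, n_rounds = 5, seed = 3)
  # one whole-chromosome row plus one region-vs-rest row per genome
  expect_equal(nrow(rep), 1 + 2 * nrow(regs))
  expect_equal(rep$comparison[1], "whole chromosomes")
  expect_true(all(rep$observed_distance[-1] >
                    rep$null_mean[-1] + 3 * rep$null_sd[-1]))

  # a region interval containing no CDS yields a flagged row, not an error
  bad <- regs
  bad$a_first <- 5000L; bad$a_last <- 5001L
  bad$b_first <- 5000L; bad$b_last <- 5001L
  rep2 <- hgt_report(sim$a, sim$b, bad, n_rounds = 2, seed = 1)
  expect_true(any(grepl("no CDS", rep2$note)))
})
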