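# Classification tibbles for fabricate_map(): a collinear backbone of n
# BBH anchors with optional modifications.
collinear_cls <- function(n, identity = 99) {
  tibble::tibble(ordinal = 0:(n - 1), class = "bbh",
                 counterpart = 0:(n - 1), identity = identity)
}

test_that("identical genomes give a perfectly collinear profile and no regions", {
  cls <- collinear_cls(30)
  map <- fabricate_map(cls, cls)
  prof <- build_profile(map)
  expect_true(all(prof$b_ordinal == prof$a_ordinal))
  expect_equal(attr(prof, "n_inversions"), 0)
  expect_equal(attr(prof, "n_translocations"), 0)
  expect_equal(nrow(call_regions(map)), 0)
})

test_that("an inverted anchor run is flagged, matching a brute-force monotone-run oracle", {
  cls <- collinear_cls(10)
  cls$counterpart[5:7] <- c(6, 5, 4)   # anchors 4-6 (0-based) reversed
  map <- fabricate_map(cls, collinear_cls(10))
  prof <- build_profile(map)
  expect_equal(attr(prof, "n_inversions"), 1)

  # oracle: longest runs of strictly decreasing counterparts
  b <- cls$counterpart
  dec_runs <- rle(diff(b) < 0)
  oracle_n <- sum(dec_runs$values & dec_runs$lengths >= 2)
  expect_equal(attr(prof, "n_inversions"), oracle_n)
  expect_true(all(prof$inverted[5:7]))

  expect_error(build_profile(fabricate_map(collinear_cls(1), collinear_cls(1))),
               "at least 2")
})

test_that("a displaced anchor run is flagged as a translocation", {
  cls <- collinear_cls(40)
  cls$counterpart[10:14] <- cls$counterpart[10:14] + 100   # jumped block
  map <- fabricate_map(cls, collinear_cls(40))
  prof <- build_profile(map)
  expect_equal(attr(prof, "n_translocations"), 1)
})

test_that("a run of unique genes with embedded low-identity BBHs is one region", {
  # 60 genes; ordinals 20..44: unique except low-identity BBHs sprinkled in
  n <- 60
  cls_a <- collinear_cls(n)
  inside <- 21:45                       # row indices (ordinals 20..44)
  cls_a$class[inside] <- "unique"
  cls_a$counterpart[inside] <- NA
  emb <- c(25, 31, 40)                  # embedded interrupting BBHs
  cls_a$class[emb] <- "bbh"
  cls_a$counterpart[emb] <- emb - 1
  cls_a$identity[emb] <- 45             # < 70: interruption, not terminator
  cls_b <- collinear_cls(n)
  cls_b$class[inside] <- "unique"; cls_b$counterpart[inside] <- NA
  cls_b$class[emb] <- "bbh"; cls_b$counterpart[emb] <- emb - 1; cls_b$identity[emb] <- 45

  regs <- call_regions(fabricate_map(cls_a, cls_b))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$a_first, 20)
  expect_equal(regs$a_last, 44)
  expect_equal(regs$n_genes_a, 25)
  expect_equal(regs$n_unique_a, 22)
  expect_equal(regs$n_bbh_a, 3)
  expect_equal(regs$n_genes_a, regs$n_unique_a + regs$n_unidirectional_a + regs$n_bbh_a)
  # bounding anchors are the innermost flanking conserved BBHs
  expect_equal(regs$a_anchor_left, "a19")
  expect_equal(regs$a_anchor_right, "a45")
})

test_that("a high-identity BBH or a long embedded run terminates the region", {
  n <- 60
  mk <- function(emb_ident, emb_at) {
    cls <- collinear_cls(n)
    inside <- 16:45
    cls$class[inside] <- "unique"; cls$counterpart[inside] <- NA
    cls$class[emb_at] <- "bbh"; cls$counterpart[emb_at] <- emb_at - 1
    cls$identity[emb_at] <- emb_ident
    cls
  }
  # a single embedded high-identity anchor splits the run into two regions
  # (each half is below min_region_genes = 20, so both are dropped at the
  # default, visible with a smaller threshold)
  cls <- mk(99, 30)
  regs <- call_regions(fabricate_map(cls, cls),
                       params = list(min_region_genes = 5L))
  expect_equal(nrow(regs), 2)
  # four consecutive low-identity anchors exceed max_bbh_interruptions = 3
  cls2 <- mk(45, 28:31)
  regs2 <- call_regions(fabricate_map(cls2, cls2),
                        params = list(min_region_genes = 5L))
  expect_equal(nrow(regs2), 2)
  # three consecutive low-identity anchors do not
  cls3 <- mk(45, 28:30)
  regs3 <- call_regions(fabricate_map(cls3, cls3),
                        params = list(min_region_genes = 5L))
  expect_equal(nrow(regs3), 1)
})

test_that("called regions are disjoint and sorted", {
  sim <- simulate_pair(default_pair_config(seed = 21))
  map <- ortholog_map(sim$a, sim$b)
  regs <- call_regions(map)
  expect_true(all(diff(regs$a_first) > 0))
  expect_true(all(regs$a_first[-1] > regs$a_last[-nrow(regs)]))
  expect_true(all(regs$b_first[-1] > regs$b_last[-nrow(regs)]))
})

test_that("a planted unique block is recovered within one gene", {
  cfg <- small_sim_config(seed = 14, n_backbone = 80,
                          regions = list(list(name = "U", n_genes = 30L,
                                              n_unique_a = 30L, n_unique_b = 10L,
                                              donor_tv = 0.3, donor_rank = 1L,
                                              insert_after = 40L,
                                              homolog_identity = c(40, 65))))
  sim <- simulate_pair(cfg)
  map <- ortholog_map(sim$a, sim$b)
  regs <- call_regions(map)
  expect_equal(nrow(regs), 1)
  expect_lte(abs(regs$a_first - sim$truth$regions$a_first), 1)
  expect_lte(abs(regs$a_last - sim$truth$regions$a_last), 1)
  expect_equal(regs$n_unique_a, sim$truth$regions$n_unique_a)
})

test_that("region calling is invariant to swapping the two genomes", {
  sim <- simulate_pair(small_sim_config(seed = 17))
  fwd <- call_regions(ortholog_map(sim$a, sim$b))
  rev <- call_regions(ortholog_map(sim$b, sim$a))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$a_first, rev$b_first)
  expect_equal(fwd$a_last, rev$b_last)
  expect_equal(fwd$n_unique_a, rev$n_unique_b)
})

test_that("region accounting reports captured unique-gene fractions", {
  sim <- simulate_pair(small_sim_config(seed = 19))
  map <- ortholog_map(sim$a, sim$b)
  regs <- call_regions(map)
  acct <- region_accounting(regs, map)
  truth <- sim$truth$regions
  a_row <- acct[acct$genome == "a", ]
  expect_equal(a_row$n_region_unique, sum(truth$n_unique_a))
  expect_equal(a_row$n_unique_total, nrow(map$unique_a))
  expect_equal(a_row$capture_fraction,
               a_row$n_region_unique / a_row$n_unique_total)

  # a region covering the whole chromosome captures every unique gene
  whole <- regs[1, ]
  whole$a_first <- 0L; whole$a_last <- max(map$cds_a$ordinal)
  whole$b_first <- 0L; whole$b_last <- max(map$cds_b$ordinal)
  acct_whole <- region_accounting(whole, map)
  expect_true(all(acct_whole$capture_fraction == 1))
})

test_that("BED export uses 0-based half-open nucleotide coordinates of bounding genes", {
  sim <- simulate_pair(small_sim_config(seed = 23))
  map <- ortholog_map(sim$a, sim$b)
  regs <- call_regions(map)
  bed <- regions_to_bed(regs, sim$a, side = "a")
  g <- sim$a$genes
  expect_equal(bed$chromStart, g$start[match(regs$a_first, g$ordinal)])
  expect_equal(bed$chromEnd, g$end[match(regs$a_last, g$ordinal)])
  expect_true(all(bed$chromEnd > bed$chromStart))
})
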