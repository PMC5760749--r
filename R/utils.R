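# Shared small helpers. Nothing here is exported.

# Total-variation distance between two frequency vectors on the same support.
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

# Deterministic derived seed for substream `i` of master seed `seed`,
# kept inside 32-bit integer range.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 10007) %% 2147483562) + 1L
}

# GC percent of a nucleotide string; ambiguity codes excluded from both
# numerator and denominator.
gc_percent <- function(seq) {
  counts <- base_counts(seq)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  100 * sum(counts[c("G", "C")]) / acgt
}

base_counts <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0, other = 0)
  tab <- table(v)
  for (b in c("A", "C", "G", "T")) {
    if (b %in% names(tab)) counts[b] <- tab[[b]]
  }
  counts["other"] <- length(v) - sum(counts[c("A", "C", "G", "T")])
  counts
}

reverse_complement <- function(seq) {
  comp <- chartr("ACGTNRYSWKMBVDHacgtnryswkmbvdh",
                 "TGCANYRSWMKVBHDtgcanyrswmkvbhd", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Translate a strand-corrected CDS nucleotide sequence with the bacterial
# code (table 11). The annotated start codon is rendered as M and the
# trailing stop codon, if present, is trimmed. Codons containing ambiguity
# codes translate to X.
translate_cds <- function(nt_seq) {
  n <- nchar(nt_seq)
  if (n %% 3 != 0) {
    abort("CDS length not divisible by 3; cannot translate")
  }
  gc11 <- codon_universe()$code
  starts <- seq(1, n, by = 3)
  cods <- substring(toupper(nt_seq), starts, starts + 2)
  aa <- unname(gc11[cods])
  aa[is.na(aa)] <- "X"
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (length(aa) > 0) aa[1] <- "M"
  paste(aa, collapse = "")
}
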