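# Shared fixtures and independent oracles.  Oracles are deliberately
# written with different algorithms (per-diagonal run-length enumeration,
# Biostrings dynamic programming, exhaustive scans) than the implementation
# paths they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# ---- oracles ---------------------------------------------------------------

# all maximal exact common substrings >= min_len, by run-length encoding of
# the per-diagonal equality vector (a maximal match is exactly a maximal
# run of equal characters along one diagonal)
mem_oracle <- function(a, b, min_len) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(bv)
  out <- list()
  for (d in (-(na - 1)):(nb - 1)) {
    i <- max(0L, -d); j <- i + d
    len <- min(na - i, nb - j)
    if (len < min_len) next
    ai <- av[(i + 1):(i + len)]; bj <- bv[(j + 1):(j + len)]
    eq <- ai == bj & ai != "N"
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths))
    keep <- which(r$values & r$lengths >= min_len)
    for (k in keep)
      out[[length(out) + 1L]] <- tibble(a_start = i + pos[k],
                                        b_start = j + pos[k],
                                        length = r$lengths[k])
  }
  if (length(out) == 0)
    return(tibble(a_start = integer(), b_start = integer(),
                  length = integer()))
  bind_rows(out) %>% arrange(a_start, b_start)
}

# global-alignment identity via Biostrings dynamic programming (gap-free
# planted windows: substitutions only, so identity = matches / length)
nw_identity_oracle <- function(q, t) {
  pa <- Biostrings::pairwiseAlignment(q, t, type = "global",
                                      gapOpening = 40, gapExtension = 40)
  100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# exhaustive tandem-period scan: every admissible period is scored by mean
# per-window identity (Hamming, exact for substitution-only fixtures); the
# smallest period reaching the floor wins
period_oracle <- function(seq, min_period = 500L, min_identity = 95,
                          min_copies = 1.5) {
  L <- nchar(seq)
  sv <- utf8ToInt(seq)
  for (P in min_period:floor(L / min_copies)) {
    nwin <- L %/% P
    if (nwin < 1) break
    ids <- numeric(0)
    pre <- sv[1:P]
    for (i in seq_len(nwin - 1)) {
      win <- sv[(i * P + 1):((i + 1) * P)]
      ids <- c(ids, 100 * mean(pre == win))
    }
    tl <- L - nwin * P
    if (tl >= min(200, 0.2 * P))
      ids <- c(ids, 100 * mean(pre[1:tl] == sv[(nwin * P + 1):L]))
    if (length(ids) > 0 && mean(ids) >= min_identity) return(P)
  }
  NULL
}

# identity of a resolved monomer against the circular truth, rotation- and
# strand-agnostic: best local alignment against the doubled truth, either
# strand, matches over monomer length
monomer_identity_to_truth <- function(mono, truth) {
  D <- paste0(truth, truth)
  band <- nchar(D) + nchar(mono)
  best <- 0
  for (t in c(D, revcomp(D))) {
    al <- circsig:::sw_band_cpp(mono, t, -band, band)
    best <- max(best, 100 * al$matches / nchar(mono))
  }
  best
}

# ---- fixture builders ------------------------------------------------------

# genome holding a single circular plasmid built from one random part
plasmid_only_genome <- function(seed, len = 3000, copy = 5) {
  u <- with_seed_local(seed, random_dna(len))
  spec <- genome_spec(
    chromosomes = list(),
    plasmids = list(list(id = "p", parts = "unit", copy_number = copy)),
    parts = tibble(id = "unit", seq = u, category = "other"))
  build_genome(spec, seed = seed)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

# random sequence pair with a planted shared block
planted_pair <- function(seed, n = 500, block = 40) {
  with_seed_local(seed, {
    a <- random_dna(n); b <- random_dna(n)
    blk <- random_dna(block)
    pa <- sample.int(n - block, 1); pb <- sample.int(n - block, 1)
    substr(a, pa, pa + block - 1) <- blk
    substr(b, pb, pb + block - 1) <- blk
    list(a = a, b = b)
  })
}

small_fey2 <- function() fey2_genome_spec(chromosome_length = 30000L)
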