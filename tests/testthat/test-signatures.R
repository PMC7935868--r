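test_that("glocal alignment finds embedded queries on both strands", {
  set.seed(100)
  q <- random_dna(600)
  t <- paste0(random_dna(1000), q, random_dna(1000))
  al <- align_glocal(q, t)
  best <- al[which.max(al$matches), ]
  expect_equal(best$identity, 100)
  expect_equal(c(best$t_lo, best$t_hi), c(1000L, 1600L))
  expect_equal(c(best$q_lo, best$q_hi), c(0L, 600L))

  t2 <- paste0(random_dna(500), revcomp(q), random_dna(500))
  al2 <- align_glocal(q, t2)
  best2 <- al2[which.max(al2$matches), ]
  expect_equal(best2$strand, "-")
  expect_equal(best2$identity, 100)

  expect_error(align_glocal(random_dna(20), t), "shorter than 50")
  expect_error(align_glocal(strrep("ACGTN", 12), t), "N")
})

test_that("glocal identity agrees with the DP oracle on planted windows (property)", {
  for (s in 1:20) {
    set.seed(2000 + s)
    qlen <- 400 + (s %% 5) * 300
    target <- random_dna(2000 + qlen)
    pos <- sample.int(1800, 1)
    q <- substring(target, pos + 1, pos + qlen)
    nsub <- s %% 8
    if (nsub > 0) {
      at <- sample(21:(qlen - 20), nsub)   # interior substitutions
      for (p in at) {
        old <- substring(q, p, p)
        substring(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    al <- align_glocal(q, target)
    best <- al[which.max(al$matches), ]
    oracle <- nw_identity_oracle(q, substring(target, pos + 1, pos + qlen))
    expect_lt(abs(best$identity - oracle), 0.1,
              label = paste("instance", s))
  }
})

test_that("signature gates: intact parts pass, truncated parts fail with diagnostics", {
  set.seed(120)
  part <- tibble::tibble(id = "partX", seq = random_dna(1000))
  asm <- circsig:::as_contigs(
    "c1", paste0(random_dna(2000), part$seq, random_dna(2000)))
  h <- search_signature(part, asm)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$qcov, 100)

  # only 90% of the part present
  asm90 <- circsig:::as_contigs(
    "c1", paste0(random_dna(2000), substring(part$seq, 1, 900),
                 random_dna(2000)))
  h90 <- search_signature(part, asm90)
  expect_equal(nrow(h90), 0L)
  d <- attr(h90, "diagnostics")
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$qcov - 90), 2)

  # multi-copy part must yield one hit per copy
  asm2 <- circsig:::as_contigs(
    c("c1", "c2"),
    c(paste0(random_dna(500), part$seq, random_dna(500)),
      paste0(random_dna(300), part$seq, random_dna(700))))
  h2 <- search_signature(part, asm2)
  expect_equal(sort(h2$contig), c("c1", "c2"))
})

test_that("parts split by small indels are chained and still pass qcov", {
  set.seed(130)
  part <- tibble::tibble(id = "p", seq = random_dna(1500))
  broken <- paste0(substring(part$seq, 1, 700), random_dna(40),
                   substring(part$seq, 701, 1500))
  asm <- circsig:::as_contigs("c", paste0(random_dna(800), broken,
                                          random_dna(800)))
  h <- search_signature(part, asm, min_identity = 90)
  expect_equal(nrow(h), 1L)
  expect_gte(h$qcov, 98)
})

test_that("feature best-hit search is deterministic under ties", {
  set.seed(140)
  cen <- tibble::tibble(id = "CEN", seq = random_dna(500),
                        category = "centromere")
  asm <- circsig:::as_contigs(
    c("a", "b"),
    c(paste0(random_dna(400), cen$seq, random_dna(400)),
      paste0(random_dna(100), cen$seq, random_dna(700))))
  h1 <- search_feature_best_hit(cen, asm)
  h2 <- search_feature_best_hit(cen, asm)
  expect_identical(h1, h2)
  expect_equal(h1$contig, "a")          # lexicographic tie-break
  expect_equal(nrow(h1), 1L)

  none <- search_feature_best_hit(
    tibble::tibble(id = "x", seq = random_dna(400)), asm)
  expect_equal(nrow(none), 0L)
})

test_that("design classifier covers the four verdicts", {
  hits <- tibble::tibble(
    signature = c("a", "b", "c"), contig = "c1",
    start = c(0L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
    strand = "+", identity = 100, qcov = 100, chained = FALSE)
  expect_equal(classify_design(c("a", "b", "c"), hits)$verdict,
               "complete_contiguous")
  expect_equal(classify_design(c("a", "b", "c"), hits[0, ])$verdict,
               "absent")
  expect_equal(classify_design(c("a", "b", "c", "d"), hits)$verdict,
               "missing_fragment")
  split_hits <- dplyr::mutate(hits, contig = c("c1", "c2", "c1"))
  expect_equal(classify_design(c("a", "b", "c"), split_hits)$verdict,
               "contig_break")
  disordered <- dplyr::mutate(hits, start = c(2000L, 1000L, 0L),
                              end = c(2500L, 1500L, 500L))
  expect_equal(classify_design(c("a", "b", "c"), disordered)$verdict,
               "contig_break")
  # minus strand: reversed order is consistent
  minus <- dplyr::mutate(disordered, strand = "-")
  expect_equal(classify_design(c("a", "b", "c"), minus)$verdict,
               "complete_contiguous")
  # circular contig: rotated order is consistent
  rot <- dplyr::mutate(hits, start = c(2000L, 0L, 1000L),
                       end = c(2500L, 500L, 1500L))
  expect_equal(classify_design(c("a", "b", "c"), rot,
                               circular_contigs = "c1")$verdict,
               "complete_contiguous")
  expect_equal(classify_design(c("a", "b", "c"), rot)$verdict,
               "contig_break")
})

test_that("annotation flags plasmid contigs by origin hits and fills the map", {
  spec <- small_fey2()
  lib <- signature_library(spec)
  g <- build_genome(spec, seed = 150)
  asm <- make_collapsed_assembly(g, seed = 150)
  an <- annotate_assembly(asm$contigs, lib)
  expect_setequal(an$plasmid_contigs, c("plasmid_low", "plasmid_high"))
  expect_true(all(an$status$verdict == "complete_contiguous"))
  expect_setequal(unique(an$contig_map$id), asm$contigs$id)

  empty_lib <- list(parts = lib$parts[0, ], constructs = lib$constructs[0, ])
  an0 <- annotate_assembly(asm$contigs, empty_lib)
  expect_equal(nrow(an0$hits), 0L)
  expect_setequal(unique(an0$contig_map$id), asm$contigs$id)
})

test_that("library FASTA and construct TSV round-trip", {
  spec <- small_fey2()
  lib <- signature_library(spec)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_signature_library(lib$parts, fa)
  back <- read_signature_library(fa)
  expect_equal(back$id, lib$parts$id)
  expect_equal(back$category, lib$parts$category)
  expect_equal(back$seq, lib$parts$seq)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(lib$constructs, tsv)
  expect_equal(as.data.frame(read_constructs(tsv)),
               as.data.frame(lib$constructs))
})
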