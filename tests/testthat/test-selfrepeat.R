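test_that("find_mems returns exactly the forced matches on tiny inputs", {
  m <- find_mems("ACGTACGT", "ACGTACGT", min_len = 4)
  expect_true(nrow(dplyr::filter(m, a_start == 0, b_start == 0,
                                 length == 8)) == 1)
  expect_true(nrow(dplyr::filter(m, a_start == 0, b_start == 4,
                                 length == 4)) == 1)
  expect_true(nrow(dplyr::filter(m, a_start == 4, b_start == 0,
                                 length == 4)) == 1)
  expect_equal(nrow(find_mems("AAAA", "TTTT", min_len = 4)), 0L)
})

test_that("find_mems equals the per-diagonal brute-force oracle (property)", {
  for (s in 1:100) {
    p <- planted_pair(seed = 1000 + s, n = 80 + (s %% 6) * 150,
                      block = 20 + (s %% 4) * 15)
    ml <- c(8L, 12L, 20L)[(s %% 3) + 1]
    got <- find_mems(p$a, p$b, min_len = ml) %>%
      dplyr::select("a_start", "b_start", "length") %>%
      dplyr::arrange(.data$a_start, .data$b_start)
    want <- mem_oracle(p$a, p$b, ml)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 label = paste("instance", s))
  }
})

test_that("reverse-strand matches are reported in forward coordinates", {
  set.seed(7)
  a <- random_dna(300)
  blk <- substring(a, 101, 160)
  b <- paste0(random_dna(80), revcomp(blk), random_dna(80))
  m <- find_mems(a, b, min_len = 30, both_strands = TRUE)
  mm <- dplyr::filter(m, strand == "-")
  expect_gte(nrow(mm), 1)
  best <- mm[which.max(mm$length), ]
  expect_equal(revcomp(substring(b, best$b_start + 1,
                                 best$b_start + best$length)),
               substring(a, best$a_start + 1, best$a_start + best$length))
})

test_that("self-repeat clusters quantify tandem structure, random contigs are clean", {
  set.seed(20)
  expect_equal(nrow(self_repeat_clusters(random_dna(10000))), 0L)

  u <- random_dna(3000)
  cl <- self_repeat_clusters(strrep(u, 3))
  expect_gte(nrow(cl), 2)
  expect_setequal(intersect(cl$offset, c(3000, 6000)), c(3000, 6000))
  expect_true(all(cl$est_identity == 100))
})

test_that("cluster identity on mutated copies matches a banded-alignment oracle", {
  for (s in 1:5) {
    g <- plasmid_only_genome(seed = 600 + s, len = 3000, copy = 2)
    asm <- make_collapsed_assembly(
      g, modes = list(p = list(mode = "collapsed_tandem", k = 3,
                               mut_rate = 0.005)), seed = 600 + s)
    ctg <- asm$contigs$seq[1]
    cl <- self_repeat_clusters(ctg, min_id = 95)
    expect_gte(nrow(cl), 1)
    oracle <- circsig:::nw_identity(substring(ctg, 1, 3000),
                                    substring(ctg, 3001, 6000))$identity
    expect_lt(abs(cl$est_identity[which.max(cl$total_len)] - oracle), 1.0)
  }
})

test_that("candidate gate honours flag, length bound and repeat coverage", {
  set.seed(33)
  u <- random_dna(3000)
  tri <- circsig:::as_contigs("t", strrep(u, 3))
  md_flag <- tibble::tibble(id = "t", length = 9000L, depth = 10,
                            circular = TRUE)
  expect_equal(is_candidate_circular(tri, md_flag),
               list(candidate = TRUE, reason = "flagged"))
  expect_equal(is_candidate_circular(tri),
               list(candidate = TRUE, reason = "repetitive"))

  big_u <- random_dna(22000)
  big <- circsig:::as_contigs("big", strrep(big_u, 3))   # 66 kb tandem
  expect_equal(is_candidate_circular(big),
               list(candidate = FALSE, reason = "no"))

  rnd <- circsig:::as_contigs("r", random_dna(9000))
  expect_equal(is_candidate_circular(rnd),
               list(candidate = FALSE, reason = "no"))
})

test_that("tandem period detection: floor rule, exact and fractional copies", {
  expect_null(detect_tandem_period(strrep("ACGT", 1000)))  # period < 500

  set.seed(44)
  u <- random_dna(3000)
  tp <- detect_tandem_period(strrep(u, 3))
  expect_equal(tp$period, 3000L)
  expect_equal(tp$copies, 3)
  expect_equal(tp$monomer_identity, 100)

  # 2.5 copies with ~1% substitutions
  copies <- as.character(circsig:::mutate_seqs_cpp(
    c(u, u, substring(u, 1, 1500)), 0.01, 0, 0))
  ctg <- paste(copies, collapse = "")
  tp2 <- detect_tandem_period(ctg)
  expect_lt(abs(tp2$period - 3000), 50)
  expect_lt(abs(tp2$copies - 2.5), 0.1)
  expect_gte(tp2$monomer_identity, 95)
})

test_that("detected period equals the exhaustive-scan oracle (property)", {
  for (s in 1:3) {
    set.seed(700 + s)
    u <- random_dna(700 + s * 150)
    copies <- as.character(circsig:::mutate_seqs_cpp(rep(u, 3), 0.01, 0, 0))
    ctg <- paste(copies, collapse = "")
    want <- period_oracle(ctg)
    got <- detect_tandem_period(ctg)
    expect_equal(got$period, want)
  }
})

test_that("monomerize corrects isolated errors by majority vote", {
  nrep <- 10
  ok <- 0
  for (s in 1:nrep) {
    g <- plasmid_only_genome(seed = 800 + s, len = 3000, copy = 2)
    truth <- g$truth$plasmids$seq[1]
    asm <- make_collapsed_assembly(
      g, modes = list(p = list(mode = "collapsed_tandem", k = 3,
                               mut_rate = 0.01)), seed = 800 + s)
    tp <- detect_tandem_period(asm$contigs[1, ])
    mono <- monomerize(asm$contigs[1, ], tp$period)
    expect_equal(nchar(mono$monomer), tp$period)   # output length == period
    if (monomer_identity_to_truth(mono$monomer, truth) >= 99.9) ok <- ok + 1
  }
  expect_gte(ok, nrep - 1)
})

test_that("canonicalization is idempotent and strand/rotation invariant", {
  set.seed(60)
  for (i in 1:10) {
    s <- random_dna(200)
    off <- sample.int(199, 1)
    rot <- paste0(substring(s, off + 1), substring(s, 1, off))
    c1 <- canonical_rotation(s)
    expect_equal(canonical_rotation(rot), c1)
    expect_equal(canonical_rotation(revcomp(rot)), c1)
    expect_equal(canonical_rotation(c1), c1)        # idempotent
  }
})

test_that("junction validation needs origin-spanning reads", {
  g <- plasmid_only_genome(seed = 70, len = 3000, copy = 1)
  truth <- g$truth$plasmids$seq[1]
  mono <- canonical_rotation(truth)
  circ_reads <- simulate_long_reads(
    truth_templates(g), long_read_params(coverage = 30, length_mean = 4000,
                                         sub_rate = 0.01, ins_rate = 0.005,
                                         del_rate = 0.005), seed = 71)
  expect_gte(validate_junction(mono, circ_reads), 1L)

  # a linearized copy cut exactly at the canonical origin: no read wraps
  lin <- tibble::tibble(id = "lin", seq = mono, circular = FALSE,
                        copy_number = 1)
  lin_reads <- simulate_long_reads(lin, long_read_params(
    coverage = 30, length_mean = 4000, sub_rate = 0.01, ins_rate = 0.005,
    del_rate = 0.005), seed = 72)
  expect_equal(validate_junction(mono, lin_reads), 0L)
  expect_equal(validate_junction(mono, circ_reads[0, ]), 0L)
})

test_that("resolve_circular prefers consensus monomers and records decisions", {
  g <- plasmid_only_genome(seed = 90, len = 3000, copy = 4)
  truth <- g$truth$plasmids$seq[1]
  asm <- make_collapsed_assembly(
    g, modes = list(p = list(mode = "collapsed_tandem", k = 3,
                             mut_rate = 0.002)), seed = 90)
  reads <- simulate_long_reads(g, long_read_params(coverage = 20,
                                                   length_mean = 4000),
                               seed = 91)
  res <- resolve_circular(asm$contigs, asm$metadata, reads)
  expect_equal(nrow(res$resolved), 1L)
  expect_equal(res$decisions$reason, "repetitive")
  expect_equal(res$decisions$period, 3000L)
  expect_gte(res$decisions$junction_support, 1L)
  expect_gte(monomer_identity_to_truth(res$resolved$seq[1], truth), 99.9)
})
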