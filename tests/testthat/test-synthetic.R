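test_that("build_genome plants features deterministically at truth coordinates", {
  spec <- genome_spec(
    chromosomes = list(list(length = 10000L, telomere_motif = "TGTGGG",
                            telomere_array_len = 300L,
                            centromere_seq = strrep("AT", 60))))
  g1 <- build_genome(spec, seed = 3)
  g2 <- build_genome(spec, seed = 3)
  expect_equal(g1$chromosomes$seq, g2$chromosomes$seq)
  expect_equal(g1$chromosomes$length, 10000L)
  # telomere arrays sit at both ends
  expect_equal(substring(g1$chromosomes$seq, 1, 6), "TGTGGG")

  g3 <- build_genome(spec, seed = 4)
  expect_false(g1$chromosomes$seq == g3$chromosomes$seq)
})

test_that("planted parts are recovered verbatim at truth intervals", {
  spec <- small_fey2()
  g <- build_genome(spec, seed = 5)
  for (i in seq_len(nrow(g$truth$parts))) {
    tr <- g$truth$parts[i, ]
    src <- if (startsWith(tr$replicon, "chr")) {
      g$chromosomes$seq[g$chromosomes$id == tr$replicon]
    } else {
      g$plasmids$seq[g$plasmids$id == tr$replicon]
    }
    expect_equal(substring(src, tr$start + 1, tr$end),
                 spec$parts$seq[spec$parts$id == tr$part_id],
                 label = tr$part_id)
  }
})

test_that("FEY2-like preset carries copy numbers 2 and 20 and shared parts", {
  g <- build_genome(fey2_genome_spec(), seed = 1)
  expect_setequal(g$truth$plasmids$copy_number, c(2, 20))
  shared <- g$truth$parts %>%
    dplyr::filter(.data$part_id %in% c("P_shared", "T_shared"))
  expect_setequal(unique(shared$replicon), c("plasmid_low", "plasmid_high"))
})

test_that("overlapping planted features are rejected", {
  spec <- genome_spec(
    chromosomes = list(list(length = 5000L, telomere_motif = "TG",
                            telomere_array_len = 100L,
                            centromere_seq = strrep("A", 200),
                            centromere_pos = 2000L,
                            tandem_arrays = list(list(unit_seq = strrep("C", 300),
                                                      copy_number = 2,
                                                      pos = 2100L)))))
  expect_error(build_genome(spec, seed = 1), "overlap")
})

test_that("zero-error long reads are exact substrings of their templates", {
  g <- plasmid_only_genome(seed = 9, len = 2000, copy = 1)
  tpl <- truth_templates(g)
  reads <- simulate_long_reads(tpl, long_read_params(
    coverage = 5, length_mean = 800, sub_rate = 0, ins_rate = 0,
    del_rate = 0, min_read = 200), seed = 10)
  doubled <- paste0(tpl$seq, tpl$seq)     # circular template
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (reads$strand[i] == "-") s <- revcomp(s)
    expect_true(grepl(s, doubled, fixed = TRUE), label = reads$id[i])
  }
})

test_that("reads from circular templates wrap the origin", {
  g <- plasmid_only_genome(seed = 12, len = 3000, copy = 1)
  reads <- simulate_long_reads(truth_templates(g), long_read_params(
    coverage = 20, length_mean = 2500, sub_rate = 0, ins_rate = 0,
    del_rate = 0), seed = 13)
  expect_true(any(reads$tstart + reads$tlen > 3000))   # wraps
  expect_true(all(reads$tlen <= 3000))                 # single traversal
})

test_that("yield is proportional to template length times copy number", {
  g <- build_genome(fey2_genome_spec(chromosome_length = 100000L), seed = 2)
  tpl <- truth_templates(g)
  reads <- simulate_long_reads(tpl, long_read_params(coverage = 30),
                               seed = 3)
  got <- reads %>%
    dplyr::group_by(.data$template) %>%
    dplyr::summarise(bp = sum(.data$tlen))
  want <- tpl %>%
    dplyr::transmute(template = .data$id,
                     expect_bp = 30 * .data$length * .data$copy_number)
  j <- dplyr::left_join(got, want, by = "template")
  expect_true(all(abs(j$bp / j$expect_bp - 1) < 0.10))
})

test_that("simulation is deterministic under a fixed seed", {
  g <- plasmid_only_genome(seed = 1, len = 1500, copy = 2)
  r1 <- simulate_long_reads(truth_templates(g), long_read_params(coverage = 10),
                            seed = 77)
  r2 <- simulate_long_reads(truth_templates(g), long_read_params(coverage = 10),
                            seed = 77)
  expect_identical(r1$seq, r2$seq)
})

test_that("short reads are inner-facing exact pairs at zero error", {
  g <- plasmid_only_genome(seed = 21, len = 5000, copy = 1)
  pr <- simulate_short_reads(truth_templates(g), short_read_params(
    coverage = 10, read_len = 100, insert_mean = 300, insert_sd = 20,
    sub_rate = 0, ins_rate = 0, del_rate = 0), seed = 22)
  doubled <- paste0(truth_templates(g)$seq, truth_templates(g)$seq)
  ok1 <- vapply(pr$r1$seq, function(s)
    grepl(s, doubled, fixed = TRUE) || grepl(revcomp(s), doubled,
                                             fixed = TRUE), logical(1))
  expect_true(all(ok1))
  expect_error(short_read_params(read_len = 150, insert_mean = 200),
               "insert_mean")
})

test_that("collapsed assembly modes produce the advertised structures", {
  g <- plasmid_only_genome(seed = 30, len = 3000, copy = 5)
  asm <- make_collapsed_assembly(
    g, modes = list(p = list(mode = "collapsed_tandem", k = 3,
                             mut_rate = 0)), base_depth = 10, seed = 30)
  expect_equal(asm$contigs$length, 9000L)
  expect_false(asm$contigs$circular)
  expect_equal(asm$metadata$depth, 50)     # copy 5 x base 10

  asm2 <- make_collapsed_assembly(g, seed = 30)
  expect_true(asm2$metadata$circular)

  expect_error(make_collapsed_assembly(
    g, modes = list(p = list(mode = "collapsed_tandem", k = 1))), "k >= 2")

  spec <- small_fey2()
  gg <- build_genome(spec, seed = 31)
  fr <- make_collapsed_assembly(
    gg, modes = list(chr_1 = list(mode = "fragmented", n = 2)), seed = 31)
  expect_equal(sum(startsWith(fr$contigs$id, "chr_1_frag")), 2L)
  # the cut splits the integration between its middle parts
  cut_at <- fr$contigs$length[fr$contigs$id == "chr_1_frag1"]
  ig <- gg$truth$parts %>% dplyr::filter(.data$replicon == "chr_1",
                                         .data$category != "other")
  expect_true(cut_at > min(ig$start) && cut_at < max(ig$end))
})

test_that("subsampling stops at the target and differs across seeds", {
  g <- plasmid_only_genome(seed = 41, len = 4000, copy = 1)
  reads <- simulate_long_reads(truth_templates(g),
                               long_read_params(coverage = 20,
                                                length_mean = 800),
                               seed = 42)
  tot <- sum(nchar(reads$seq))
  expect_identical(subsample_reads(reads, target_bp = tot, seed = 1), reads)
  half <- subsample_reads(reads, target_bp = round(tot / 2), seed = 1)
  got <- sum(nchar(half$seq))
  expect_true(got >= tot / 2 && got < tot / 2 + max(nchar(reads$seq)))
  other <- subsample_reads(reads, target_bp = round(tot / 2), seed = 2)
  expect_false(identical(half$id, other$id))
  expect_error(subsample_reads(reads, target_bp = tot + 1), "exceeds")
})

test_that("metagenome mixing hits the requested base-pair ratio", {
  g <- plasmid_only_genome(seed = 51, len = 4000, copy = 1)
  focal <- simulate_long_reads(truth_templates(g),
                               long_read_params(coverage = 10,
                                                length_mean = 800),
                               seed = 52)
  bgg <- background_genomes(n = 2, size = 50000, seed = 53)
  bg <- simulate_long_reads(
    dplyr::mutate(bgg, circular = FALSE, copy_number = 1),
    long_read_params(coverage = 10, length_mean = 800), seed = 54)
  fb <- sum(nchar(focal$seq))
  mixed <- mix_metagenome(focal, bg, ratio = 3, seed = 55)
  bg_bp <- sum(nchar(mixed$seq)) - fb
  expect_true(abs(bg_bp - 3 * fb) <= max(nchar(bg$seq)))
  expect_identical(mix_metagenome(focal, bg, ratio = 0), focal)
  expect_error(mix_metagenome(focal, bg, ratio = 1e6, seed = 1),
               "insufficient background")
})
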