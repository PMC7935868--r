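# Seeded synthetic genomes, reads, collapsed assemblies and metagenome
# mixtures.  Everything is deterministic under a fixed seed, and every
# planted feature is reported in a ground-truth table so downstream stages
# can be tested by parameter recovery.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic engineered genome
#'
#' A genome spec lists linear chromosomes (with terminal telomere arrays, a
#' centromere and optional tandem arrays), planted part runs (engineering
#' integrations or native single-copy loci), circular plasmids built by
#' concatenating parts at a stated copy number per genome equivalent, and
#' the part library itself.
#'
#' @param chromosomes List of chromosome specs; each a list with `length`,
#'   `telomere_motif`, `telomere_array_len`, `centromere_seq`, optional
#'   `centromere_pos` (default: centre), and optional `tandem_arrays`, a
#'   list of `list(unit_seq =, copy_number =, pos =)`.
#' @param integrations List of planted part runs: `list(chromosome =, pos =,
#'   parts = c(...))`.  Parts are placed in order on the forward strand.
#' @param plasmids List of `list(id =, parts = c(...), copy_number =)`.
#' @param parts Tibble with columns `id`, `seq`, `category`.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, integrations = list(), plasmids = list(),
                        parts = tibble::tibble(id = character(),
                                               seq = character(),
                                               category = character())) {
  stopifnot(all(c("id", "seq", "category") %in% names(parts)))
  used <- unique(c(unlist(lapply(integrations, `[[`, "parts")),
                   unlist(lapply(plasmids, `[[`, "parts"))))
  unknown <- setdiff(used, parts$id)
  if (length(unknown) > 0)
    stop("unresolved part id(s): ", paste(unknown, collapse = ", "))
  for (p in plasmids)
    if (is.null(p$copy_number) || p$copy_number < 1)
      stop("plasmid copy_number must be >= 1")
  structure(list(chromosomes = chromosomes, integrations = integrations,
                 plasmids = plasmids, parts = parts),
            class = "genome_spec")
}

preset_parts <- function() {
  lens <- c(P_shared = 600, T_shared = 300,
            crtE_like = 1200, crtYB_like = 1500, crtI_like = 1100,
            marker_hyg = 1000, ori_cen6 = 500, marker_kan = 1000,
            dcas9_like = 2000, ori_2mu = 600, marker_nat = 1000,
            grna_cassette = 300, act1_like = 1000)
  cats <- c(P_shared = "promoter", T_shared = "terminator",
            crtE_like = "CDS", crtYB_like = "CDS", crtI_like = "CDS",
            marker_hyg = "marker", ori_cen6 = "origin", marker_kan = "marker",
            dcas9_like = "CDS", ori_2mu = "origin", marker_nat = "marker",
            grna_cassette = "gRNA", act1_like = "other")
  with_local_seed(104729, {
    tibble::tibble(id = names(lens),
                   seq = unname(vapply(lens, random_dna, character(1))),
                   category = unname(cats[names(lens)]))
  })
}

#' FEY2-like genome preset
#'
#' A documented preset mirroring a heavily engineered baker's-yeast strain:
#' one chromosome carrying a four-part carotenoid-pathway-like integration
#' and a single-copy ACT1-like locus, a low-copy (CEN6/ARSH4-like origin)
#' plasmid at copy number 2 and a high-copy (2-micron-like origin) plasmid
#' at copy number 20, the two plasmids sharing one promoter and one
#' terminator part.  Copy numbers 2 and 20 are the approximate per-cell
#' copy numbers of those origins.
#'
#' @param chromosome_length Chromosome length in bases (default 200 kb).
#' @return A `genome_spec`.
#' @export
fey2_genome_spec <- function(chromosome_length = 200000L) {
  L <- as.integer(chromosome_length)
  parts <- preset_parts()
  cen <- with_local_seed(224737, random_dna(120))
  genome_spec(
    chromosomes = list(list(
      length = L, telomere_motif = "TGTGGGTGTGGTG",
      telomere_array_len = 2000L, centromere_seq = cen,
      centromere_pos = as.integer(0.6 * L))),
    integrations = list(
      list(chromosome = 1L, pos = as.integer(0.3 * L),
           parts = c("crtE_like", "crtYB_like", "crtI_like", "marker_hyg")),
      list(chromosome = 1L, pos = as.integer(0.5 * L), parts = "act1_like")),
    plasmids = list(
      list(id = "plasmid_low", copy_number = 2,
           parts = c("ori_cen6", "marker_kan", "P_shared", "dcas9_like",
                     "T_shared")),
      list(id = "plasmid_high", copy_number = 20,
           parts = c("ori_2mu", "marker_nat", "P_shared", "grna_cassette",
                     "T_shared"))),
    parts = parts)
}

#' FEY15-like genome preset
#'
#' A leaner engineered-strain preset used for spike-in detection studies:
#' one chromosome with a four-part regulator integration and the ACT1-like
#' single-copy locus, plus one high-copy gRNA-expression plasmid sharing
#' promoter/terminator parts with the integration.
#'
#' @param chromosome_length Chromosome length in bases (default 500 kb).
#' @return A `genome_spec`.
#' @export
fey15_genome_spec <- function(chromosome_length = 500000L) {
  L <- as.integer(chromosome_length)
  parts <- preset_parts()
  cen <- with_local_seed(224737, random_dna(120))
  genome_spec(
    chromosomes = list(list(
      length = L, telomere_motif = "TGTGGGTGTGGTG",
      telomere_array_len = 2000L, centromere_seq = cen,
      centromere_pos = as.integer(0.6 * L))),
    integrations = list(
      list(chromosome = 1L, pos = as.integer(0.3 * L),
           parts = c("P_shared", "dcas9_like", "T_shared", "marker_nat")),
      list(chromosome = 1L, pos = as.integer(0.5 * L), parts = "act1_like")),
    plasmids = list(
      list(id = "plasmid_grna", copy_number = 20,
           parts = c("ori_2mu", "marker_kan", "P_shared", "grna_cassette",
                     "T_shared"))),
    parts = parts)
}

#' Signature library and construct definitions for a genome spec
#'
#' @param spec A `genome_spec`.
#' @return List with `parts` (tibble `id`, `seq`, `category`) and
#'   `constructs` (tibble `construct`, `parts` comma-separated in order).
#' @export
signature_library <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  native <- vapply(spec$integrations, function(x) length(x$parts) == 1 &&
                     spec$parts$category[match(x$parts, spec$parts$id)] == "other",
                   logical(1))
  constructs <- c(
    lapply(which(!native), function(i)
      list(construct = paste0("integration_", i),
           parts = spec$integrations[[i]]$parts)),
    lapply(spec$plasmids, function(p)
      list(construct = p$id, parts = p$parts)))
  tibble::tibble(
    construct = vapply(constructs, `[[`, character(1), "construct"),
    parts = vapply(constructs, function(x) paste(x$parts, collapse = ","),
                   character(1))) -> ctab
  list(parts = spec$parts, constructs = ctab)
}

#' Build a synthetic genome from a spec
#'
#' Chromosome backbones are i.i.d. uniform DNA; telomere arrays, the
#' centromere, tandem arrays and part runs overwrite the backbone at their
#' stated positions (so coordinates in the truth table locate the planted
#' sequences exactly).  Plasmid sequences are part concatenations.
#'
#' @param spec A `genome_spec`.
#' @param seed Integer seed; output is fully deterministic given it.
#' @return List with `chromosomes` and `plasmids` contig tibbles and a
#'   `truth` list (`parts`, `plasmids`, `arrays`, `chromosomes`, `seed`).
#' @export
build_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed)
  part_seq <- stats::setNames(spec$parts$seq, spec$parts$id)
  part_cat <- stats::setNames(spec$parts$category, spec$parts$id)
  chrom_ids <- paste0("chr_", seq_along(spec$chromosomes))
  truth_parts <- list(); truth_arrays <- list()
  chrom_seqs <- character(length(spec$chromosomes))
  for (ci in seq_along(spec$chromosomes)) {
    ch <- spec$chromosomes[[ci]]
    L <- as.integer(ch$length)
    seq <- random_dna(L)
    feats <- list()   # (start, end, seq, label, category)
    tl <- as.integer(ch$telomere_array_len %||% 0L)
    if (tl > 0) {
      tel <- strtrim(strrep(ch$telomere_motif, ceiling(tl / nchar(ch$telomere_motif))), tl)
      feats <- c(feats, list(list(0L, tl, tel, "telomere_left", "telomere"),
                             list(L - tl, L, revcomp(tel), "telomere_right",
                                  "telomere")))
    }
    if (!is.null(ch$centromere_seq)) {
      cp <- as.integer(ch$centromere_pos %||% (L %/% 2L))
      feats <- c(feats, list(list(cp, cp + nchar(ch$centromere_seq),
                                  ch$centromere_seq, "centromere", "centromere")))
    }
    for (ai in seq_along(ch$tandem_arrays %||% list())) {
      ta <- ch$tandem_arrays[[ai]]
      arr <- strrep(ta$unit_seq, ta$copy_number)
      feats <- c(feats, list(list(as.integer(ta$pos),
                                  as.integer(ta$pos) + nchar(arr), arr,
                                  paste0("array_", ci, "_", ai), "array")))
      truth_arrays[[length(truth_arrays) + 1L]] <- tibble::tibble(
        array_id = paste0("array_", ci, "_", ai), replicon = chrom_ids[ci],
        unit_seq = ta$unit_seq, start = as.integer(ta$pos),
        end = as.integer(ta$pos) + nchar(arr), copy_number = ta$copy_number)
    }
    for (ii in seq_along(spec$integrations)) {
      ig <- spec$integrations[[ii]]
      if (ig$chromosome != ci) next
      pos <- as.integer(ig$pos)
      for (pid in ig$parts) {
        ps <- part_seq[[pid]]
        feats <- c(feats, list(list(pos, pos + nchar(ps), ps, pid,
                                    part_cat[[pid]])))
        truth_parts[[length(truth_parts) + 1L]] <- tibble::tibble(
          part_id = pid, category = part_cat[[pid]], replicon = chrom_ids[ci],
          start = pos, end = pos + nchar(ps), strand = "+")
        pos <- pos + nchar(ps)
      }
    }
    if (length(feats) > 0) {
      st <- vapply(feats, function(f) f[[1]], integer(1))
      en <- vapply(feats, function(f) f[[2]], integer(1))
      if (any(st < 0) || any(en > L))
        stop("planted feature outside chromosome bounds on ", chrom_ids[ci])
      o <- order(st)
      if (any(st[o][-1] < en[o][-length(o)]))
        stop("overlapping planted features on ", chrom_ids[ci])
      for (f in feats)
        substr(seq, f[[1]] + 1L, f[[2]]) <- f[[3]]
    }
    chrom_seqs[ci] <- seq
  }
  plasmid_tab <- lapply(spec$plasmids, function(p) {
    pos <- 0L
    for (pid in p$parts) {
      ps <- part_seq[[pid]]
      truth_parts[[length(truth_parts) + 1L]] <<- tibble::tibble(
        part_id = pid, category = part_cat[[pid]], replicon = p$id,
        start = pos, end = pos + nchar(ps), strand = "+")
      pos <- pos + nchar(ps)
    }
    tibble::tibble(id = p$id, seq = paste(part_seq[p$parts], collapse = ""),
                   copy_number = p$copy_number)
  })
  plasmid_tab <- dplyr::bind_rows(plasmid_tab)
  if (nrow(plasmid_tab) == 0)
    plasmid_tab <- tibble::tibble(id = character(), seq = character(),
                                  copy_number = numeric())
  truth <- list(
    parts = dplyr::bind_rows(truth_parts),
    plasmids = plasmid_tab,
    arrays = dplyr::bind_rows(truth_arrays),
    chromosomes = tibble::tibble(
      id = chrom_ids,
      length = vapply(spec$chromosomes, function(x) as.integer(x$length),
                      integer(1))),
    seed = seed)
  list(
    chromosomes = as_contigs(chrom_ids, chrom_seqs),
    plasmids = as_contigs(plasmid_tab$id, plasmid_tab$seq,
                          circular = TRUE) %>%
      dplyr::mutate(copy_number = plasmid_tab$copy_number),
    truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Templates for read simulation
#'
#' Collects chromosomes (copy 1, linear) and plasmids (their copy numbers,
#' circular) from a built genome into one template table.
#'
#' @param genome Result of [build_genome()].
#' @return Tibble with `id`, `seq`, `length`, `circular`, `copy_number`.
#' @export
truth_templates <- function(genome) {
  dplyr::bind_rows(
    genome$chromosomes %>%
      dplyr::mutate(circular = FALSE, copy_number = 1) %>%
      dplyr::select("id", "seq", "length", "circular", "copy_number"),
    genome$plasmids %>%
      dplyr::select("id", "seq", "length", "circular", "copy_number"))
}

#' Long-read simulation parameters
#'
#' Read lengths follow a log-normal with the given mean and multiplicative
#' sd factor, truncated to the template length (a read traverses a circular
#' template's origin at most once, as tagmentation of a monomeric circle
#' linearizes it at a single point).  Errors are i.i.d. per base.
#'
#' @param coverage Target depth per genome equivalent (x).
#' @param length_mean,length_sd_factor Log-normal read-length model.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities, each in
#'   \[0, 0.2\].
#' @param min_read Minimum simulated read length.
#' @return A parameter list.
#' @export
long_read_params <- function(coverage = 50, length_mean = 8000,
                             length_sd_factor = 1.6, sub_rate = 0.03,
                             ins_rate = 0.03, del_rate = 0.03,
                             min_read = 500) {
  stopifnot(coverage > 0, length_mean > 0, length_sd_factor >= 1,
            sub_rate >= 0, sub_rate <= 0.2, ins_rate >= 0, ins_rate <= 0.2,
            del_rate >= 0, del_rate <= 0.2)
  list(type = "long", coverage = coverage, length_mean = length_mean,
       length_sd_factor = length_sd_factor, sub_rate = sub_rate,
       ins_rate = ins_rate, del_rate = del_rate, min_read = min_read)
}

#' Short-read simulation parameters
#'
#' @param coverage Target depth per genome equivalent (x), counting both
#'   mates.
#' @param read_len Read length per mate.
#' @param insert_mean,insert_sd Normal insert-size model; `insert_mean`
#'   must be at least `2 * read_len`.
#' @inheritParams long_read_params
#' @return A parameter list.
#' @export
short_read_params <- function(coverage = 50, read_len = 150,
                              insert_mean = 400, insert_sd = 40,
                              sub_rate = 0.001, ins_rate = 0.0001,
                              del_rate = 0.0001) {
  stopifnot(coverage > 0, sub_rate >= 0, sub_rate <= 0.2,
            ins_rate >= 0, ins_rate <= 0.2, del_rate >= 0, del_rate <= 0.2)
  if (insert_mean < 2 * read_len)
    stop("insert_mean must be at least 2 * read_len")
  list(type = "short", coverage = coverage, read_len = read_len,
       insert_mean = insert_mean, insert_sd = insert_sd, sub_rate = sub_rate,
       ins_rate = ins_rate, del_rate = del_rate)
}

draw_template_reads <- function(tpl, params) {
  L <- nchar(tpl$seq)
  target <- params$coverage * L * tpl$copy_number
  sdlog <- log(params$length_sd_factor)
  meanlog <- log(params$length_mean) - sdlog^2 / 2
  starts <- integer(0); lens <- integer(0); tot <- 0
  while (tot < target) {
    n <- max(16L, ceiling((target - tot) / params$length_mean * 1.3))
    ln <- pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)),
                    min(params$min_read, L)), L)
    st <- sample.int(L, n, replace = TRUE) - 1L
    if (!tpl$circular) ln <- pmin(ln, L - st)
    keep <- cumsum(ln) <= (target - tot) + ln  # stop after crossing target
    nkeep <- max(1L, sum(cumsum(ln) - ln < target - tot))
    st <- st[seq_len(nkeep)]; ln <- ln[seq_len(nkeep)]
    starts <- c(starts, st); lens <- c(lens, ln); tot <- tot + sum(ln)
  }
  src <- if (tpl$circular) paste0(tpl$seq, tpl$seq) else tpl$seq
  seqs <- substring(src, starts + 1L, starts + lens)
  rev <- stats::runif(length(seqs)) < 0.5
  seqs[rev] <- revcomp(seqs[rev])
  tibble::tibble(template = tpl$id, tstart = starts, tlen = lens,
                 strand = ifelse(rev, "-", "+"), seq = seqs)
}

#' Simulate long reads
#'
#' Per-template expected base yield is proportional to template length
#' times copy number.  Reads from circular templates start uniformly on the
#' circle and wrap the origin; linear-template reads are truncated at the
#' template end.
#'
#' @param templates Template tibble from [truth_templates()] (columns `id`,
#'   `seq`, `circular`, `copy_number`), or a built genome.
#' @param params From [long_read_params()].
#' @param seed Integer seed.
#' @return Read tibble (`id`, `seq`, `qual`, `platform`) with simulation
#'   truth columns (`template`, `tstart`, `tlen`, `strand`).
#' @export
simulate_long_reads <- function(templates, params = long_read_params(),
                                seed = 1L) {
  if (is.list(templates) && !is.data.frame(templates) &&
      !is.null(templates$chromosomes))
    templates <- truth_templates(templates)
  stopifnot(params$type == "long")
  set.seed(seed)
  out <- lapply(seq_len(nrow(templates)), function(i)
    draw_template_reads(templates[i, ], params))
  out <- dplyr::bind_rows(out)
  if (params$sub_rate + params$ins_rate + params$del_rate > 0)
    out$seq <- as.character(
      mutate_seqs_cpp(out$seq, params$sub_rate, params$ins_rate,
                      params$del_rate))
  out %>%
    dplyr::mutate(id = sprintf("%s_read_%06d", .data$template,
                               seq_len(nrow(out))),
                  qual = NA_character_, platform = "long") %>%
    dplyr::select("id", "seq", "qual", "platform", "template", "tstart",
                  "tlen", "strand")
}

#' Simulate paired short reads
#'
#' Inner-facing mate pairs with normal insert sizes; the same copy-number
#' weighting and circular wrap rules as long reads.
#'
#' @inheritParams simulate_long_reads
#' @param params From [short_read_params()].
#' @return List with tibbles `r1` and `r2` (platforms `short_r1`,
#'   `short_r2`), rows paired by position.
#' @export
simulate_short_reads <- function(templates, params = short_read_params(),
                                 seed = 1L) {
  if (is.list(templates) && !is.data.frame(templates) &&
      !is.null(templates$chromosomes))
    templates <- truth_templates(templates)
  stopifnot(params$type == "short")
  set.seed(seed)
  rl <- params$read_len
  sim_one <- function(tpl) {
    L <- nchar(tpl$seq)
    if (L < params$insert_mean) return(NULL)
    target <- params$coverage * L * tpl$copy_number
    n <- ceiling(target / (2 * rl))
    ins <- pmin(pmax(round(stats::rnorm(n, params$insert_mean,
                                        params$insert_sd)), 2 * rl), L)
    maxstart <- if (tpl$circular) L else L - ins + 1L
    st <- floor(stats::runif(n) * maxstart)
    src <- if (tpl$circular) paste0(tpl$seq, tpl$seq) else tpl$seq
    r1 <- substring(src, st + 1L, st + rl)
    r2 <- revcomp(substring(src, st + ins - rl + 1L, st + ins))
    flip <- stats::runif(n) < 0.5        # which physical strand was read
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    tibble::tibble(template = tpl$id, tstart = st, insert = ins, r1 = r1,
                   r2 = r2)
  }
  pairs <- dplyr::bind_rows(
    lapply(seq_len(nrow(templates)), function(i) sim_one(templates[i, ])))
  mut <- function(x) as.character(
    mutate_seqs_cpp(x, params$sub_rate, params$ins_rate, params$del_rate))
  ids <- sprintf("%s_pair_%06d", pairs$template, seq_len(nrow(pairs)))
  list(
    r1 = tibble::tibble(id = ids, seq = mut(pairs$r1), qual = NA_character_,
                        platform = "short_r1", template = pairs$template,
                        tstart = pairs$tstart, insert = pairs$insert),
    r2 = tibble::tibble(id = ids, seq = mut(pairs$r2), qual = NA_character_,
                        platform = "short_r2", template = pairs$template,
                        tstart = pairs$tstart, insert = pairs$insert))
}

#' Emit an assembler-like (possibly collapsed) assembly of a genome
#'
#' Chromosomes become linear contigs.  Each plasmid is emitted according to
#' its mode: `faithful_circular` (rotated monomer, circular flag set),
#' `collapsed_tandem` (k concatenated monomer copies, each independently
#' substituted at `mut_rate`, circular flag unset — the classic long-read
#' assembler artifact), `fragmented` (n pieces), or `missing_fragment` (a
#' named part's interval deleted).  `fragmented` and `missing_fragment`
#' also apply to chromosomes; a fragmenting cut is placed between the two
#' middle planted parts so constructs break without truncating a part.
#'
#' @param genome Result of [build_genome()].
#' @param modes Named list keyed by replicon id, e.g.
#'   `list(plasmid_low = list(mode = "collapsed_tandem", k = 3, mut_rate
#'   = 0.01))`.  Unlisted chromosomes are faithful linear contigs;
#'   unlisted plasmids are `faithful_circular`.
#' @param base_depth Assembler-reported depth for single-copy sequence.
#' @param seed Seed for rotations and collapse mutations.
#' @return List with `contigs` and `metadata` tibbles.
#' @export
make_collapsed_assembly <- function(genome, modes = list(), base_depth = 30,
                                    seed = 1L) {
  set.seed(seed)
  truth <- genome$truth
  out <- list()
  emit <- function(id, seq, depth, circular) {
    out[[length(out) + 1L]] <<- tibble::tibble(id = id, seq = seq,
                                               depth = depth,
                                               circular = circular)
  }
  fragment_cuts <- function(rep_id, L, n) {
    pp <- truth$parts %>% dplyr::filter(.data$replicon == rep_id) %>%
      dplyr::arrange(.data$start)
    if (nrow(pp) >= 2) {
      m <- nrow(pp) %/% 2
      first <- as.integer((pp$end[m] + pp$start[m + 1]) %/% 2)
    } else first <- L %/% 2L
    cuts <- first
    if (n > 2) cuts <- sort(unique(c(cuts, round(seq(1, L - 1,
                                                     length.out = n + 1)[2:n]))))
    sort(unique(pmin(pmax(cuts[seq_len(n - 1)], 1L), L - 1L)))
  }
  apply_mode <- function(id, seq, copy, is_plasmid, mode) {
    L <- nchar(seq)
    kind <- if (is.null(mode)) {
      if (is_plasmid) "faithful_circular" else "faithful_linear"
    } else mode$mode
    depth <- copy * base_depth
    if (kind == "faithful_linear") {
      emit(id, seq, depth, FALSE)
    } else if (kind == "faithful_circular") {
      off <- sample.int(L, 1) - 1L
      rot <- if (off == 0) seq else
        paste0(substring(seq, off + 1), substring(seq, 1, off))
      emit(id, rot, depth, TRUE)
    } else if (kind == "collapsed_tandem") {
      if (is.null(mode$k) || mode$k < 2)
        stop("collapsed_tandem requires k >= 2")
      mut <- mode$mut_rate %||% 0
      off <- sample.int(L, 1) - 1L
      rot <- if (off == 0) seq else
        paste0(substring(seq, off + 1), substring(seq, 1, off))
      copies <- as.character(mutate_seqs_cpp(rep(rot, mode$k), mut, 0, 0))
      emit(id, paste(copies, collapse = ""), depth, FALSE)
    } else if (kind == "fragmented") {
      n <- mode$n %||% 2L
      cuts <- fragment_cuts(id, L, n)
      bounds <- c(0L, cuts, L)
      for (i in seq_len(length(bounds) - 1L))
        emit(paste0(id, "_frag", i),
             substring(seq, bounds[i] + 1L, bounds[i + 1L]), depth, FALSE)
    } else if (kind == "missing_fragment") {
      iv <- if (!is.null(mode$part)) {
        row <- truth$parts %>%
          dplyr::filter(.data$replicon == id, .data$part_id == mode$part)
        if (nrow(row) == 0) stop("part ", mode$part, " not on ", id)
        c(row$start[1], row$end[1])
      } else c(mode$start, mode$end)
      emit(id, paste0(substring(seq, 1, iv[1]), substring(seq, iv[2] + 1L)),
           depth, is_plasmid)
    } else stop("unknown assembly mode: ", kind)
  }
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes[i, ]
    apply_mode(ch$id, ch$seq, 1, FALSE, modes[[ch$id]])
  }
  for (i in seq_len(nrow(genome$plasmids))) {
    pl <- genome$plasmids[i, ]
    apply_mode(pl$id, pl$seq, pl$copy_number, TRUE, modes[[pl$id]])
  }
  tab <- dplyr::bind_rows(out)
  contigs <- as_contigs(tab$id, tab$seq, depth = tab$depth,
                        circular = tab$circular)
  list(contigs = contigs,
       metadata = contigs %>% dplyr::select("id", "length", "depth",
                                            "circular"))
}

#' Subsample reads to a base-pair target
#'
#' Uniform sampling without replacement until the cumulative base count
#' reaches the target; deterministic per seed.
#'
#' @param reads Read tibble.
#' @param target_bp Target in bases; alternatively give `coverage` and
#'   `genome_size`.
#' @param coverage,genome_size Alternative target specification.
#' @param seed Integer seed.
#' @return Subsampled read tibble.
#' @export
subsample_reads <- function(reads, target_bp = NULL, coverage = NULL,
                            genome_size = NULL, seed = 1L) {
  if (is.null(target_bp)) {
    stopifnot(!is.null(coverage), !is.null(genome_size))
    target_bp <- coverage * genome_size
  }
  lens <- nchar(reads$seq)
  if (target_bp > sum(lens))
    stop("subsample target ", target_bp, " bp exceeds available ",
         sum(lens), " bp")
  set.seed(seed)
  o <- sample.int(nrow(reads))
  keep <- o[cumsum(lens[o]) - lens[o] < target_bp]
  reads[sort(keep), ]
}

#' Background metagenome genomes
#'
#' Random "species" genomes used as desk-test background for spike-in
#' dilution experiments; composition is irrelevant to the detection logic.
#'
#' @param n Number of species.
#' @param size Genome size per species, bases.
#' @param seed Integer seed.
#' @return Contig tibble.
#' @export
background_genomes <- function(n = 3L, size = 1e6, seed = 99L) {
  set.seed(seed)
  as_contigs(paste0("species_", seq_len(n)),
             vapply(seq_len(n), function(i) random_dna(size), character(1)))
}

#' Dilute focal reads with metagenome background
#'
#' Background reads are subsampled to `ratio` times the focal base count
#' and the pool is shuffled.  `ratio = 0` returns the focal reads
#' unchanged.
#'
#' @param focal_reads,background_reads Read tibbles.
#' @param ratio Background:focal base-pair ratio (>= 0).
#' @param seed Integer seed.
#' @return Mixed, shuffled read tibble.
#' @export
mix_metagenome <- function(focal_reads, background_reads, ratio, seed = 1L) {
  stopifnot(ratio >= 0)
  if (ratio == 0) return(focal_reads)
  focal_bp <- sum(nchar(focal_reads$seq))
  need <- round(ratio * focal_bp)
  avail <- sum(nchar(background_reads$seq))
  if (avail < need)
    stop("insufficient background reads: need ", need, " bp, have ",
         avail, " bp")
  bg <- subsample_reads(background_reads, target_bp = need, seed = seed)
  common <- intersect(names(focal_reads), names(bg))
  mixed <- dplyr::bind_rows(focal_reads[common], bg[common])
  set.seed(seed + 1L)
  mixed[sample.int(nrow(mixed)), ]
}
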