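# Telomere/centromere scanning and telomere-to-telomere completeness.

#' Scan a contig's ends for telomeric sequence
#'
#' Two modes.  Alignment mode (`telomere_seq`): presence requires a glocal
#' alignment of at least 100 matched bases at 80% identity or better whose
#' nearest edge lies within `end_window` of the respective contig end.
#' Motif mode (`motif`): presence requires exact tandem-motif coverage of
#' at least 30% of the terminal 500-bp window (either strand).
#'
#' @param contig DNA string or one-row contig tibble.
#' @param telomere_seq Telomere repeat array sequence (alignment mode).
#' @param motif Short telomere motif (motif mode).
#' @param end_window Distance from a contig end still counted as terminal.
#' @return List with logicals `left` and `right`.
#' @export
scan_telomeres <- function(contig, telomere_seq = NULL, motif = NULL,
                           end_window = 10000L) {
  seq <- get_seq(contig)
  L <- nchar(seq)
  stopifnot(end_window <= L / 2)
  if (!is.null(motif)) {
    cov_frac <- function(win) {
      covered <- function(s, m) {
        hits <- gregexpr(m, s, fixed = TRUE)[[1]]
        if (hits[1] == -1) return(0L)
        interval_union_len(as.integer(hits) - 1L,
                           as.integer(hits) - 1L + nchar(m))
      }
      max(covered(win, motif), covered(win, revcomp(motif))) / nchar(win)
    }
    wl <- substring(seq, 1, min(500L, L))
    wr <- substring(seq, max(1L, L - 500L + 1L), L)
    return(list(left = cov_frac(wl) >= 0.30, right = cov_frac(wr) >= 0.30))
  }
  stopifnot(!is.null(telomere_seq))
  al <- align_glocal(telomere_seq, seq, min_report = 80)
  al <- al[(al$t_hi - al$t_lo) >= 100 & al$identity >= 80, , drop = FALSE]
  list(left = any(al$t_lo <= end_window),
       right = any(L - al$t_hi <= end_window))
}

#' Telomere-to-telomere completeness report
#'
#' Each reference chromosome is matched to the single contig covering the
#' largest aligned fraction of it (union of maximal exact matches, seed
#' >= `min_seed`).  A chromosome is complete when one contig covers at
#' least `min_frac` of it and the chromosome's centromere locates to that
#' contig.  Telomere presence is reported alongside but not required —
#' telomere arrays are the one feature long-read assemblies routinely fail
#' to finish.
#'
#' @param assembly Contig tibble.
#' @param reference_chromosomes Contig tibble of reference chromosomes.
#' @param features Feature tibble (`id`, `seq`, `category`) containing
#'   centromeres (and optionally telomere arrays).
#' @param min_seed Minimum exact-match seed for coverage, bases.
#' @param min_frac Single-contig coverage threshold for completeness.
#' @param telomere_motif Optional motif for motif-mode telomere scanning.
#' @return Object of class `circsig_t2t`: list with `chromosomes` tibble
#'   and `percent_complete`.
#' @export
t2t_completeness <- function(assembly, reference_chromosomes, features,
                             min_seed = 500L, min_frac = 0.95,
                             telomere_motif = NULL) {
  if (is.null(reference_chromosomes) || nrow(reference_chromosomes) == 0)
    stop("reference chromosomes required")
  cens <- features[features$category == "centromere", , drop = FALSE]
  # place each centromere on the reference and on the assembly
  cen_ref <- cen_asm <- stats::setNames(character(nrow(cens)), cens$id)
  for (i in seq_len(nrow(cens))) {
    hr <- search_feature_best_hit(cens[i, ], reference_chromosomes)
    ha <- search_feature_best_hit(cens[i, ], assembly)
    cen_ref[i] <- if (nrow(hr)) hr$contig else NA_character_
    cen_asm[i] <- if (nrow(ha)) ha$contig else NA_character_
  }
  tels <- features[features$category == "telomere", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(reference_chromosomes))) {
    rc <- reference_chromosomes[i, ]
    best_id <- NA_character_; best_frac <- 0
    for (j in seq_len(nrow(assembly))) {
      m <- find_mems(rc$seq, assembly$seq[j], min_len = min_seed,
                     both_strands = TRUE)
      frac <- if (nrow(m) == 0) 0 else
        interval_union_len(m$a_start, m$a_start + m$length) / rc$length
      if (frac > best_frac) { best_frac <- frac; best_id <- assembly$id[j] }
    }
    my_cens <- names(cen_ref)[!is.na(cen_ref) & cen_ref == rc$id]
    has_cen <- length(my_cens) > 0 && !is.na(best_id) &&
      any(cen_asm[my_cens] == best_id, na.rm = TRUE)
    tel_l <- tel_r <- NA
    if (!is.na(best_id)) {
      ct <- assembly[assembly$id == best_id, ]
      ew <- min(10000L, ct$length %/% 2L)
      tl <- if (!is.null(telomere_motif))
        scan_telomeres(ct, motif = telomere_motif, end_window = ew)
      else if (nrow(tels) > 0)
        scan_telomeres(ct, telomere_seq = tels$seq[1], end_window = ew)
      else NULL
      if (!is.null(tl)) { tel_l <- tl$left; tel_r <- tl$right }
    }
    rows[[i]] <- tibble::tibble(
      chromosome = rc$id, best_contig = best_id,
      covered_fraction = best_frac, has_centromere = has_cen,
      telomere_left = tel_l, telomere_right = tel_r,
      complete = best_frac >= min_frac & has_cen)
  }
  tab <- dplyr::bind_rows(rows)
  structure(list(chromosomes = tab,
                 percent_complete = 100 * mean(tab$complete)),
            class = "circsig_t2t")
}
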