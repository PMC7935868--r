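# Engineering-signature search and construct failure-mode classification.
# Parts are located with a seed-and-extend glocal aligner and accepted under
# BLAST-style identity and query-coverage gates (defaults 98/98); genome
# features use a single best-hit search with no gates.

FEATURE_CATEGORIES <- c("telomere", "centromere", "mitochondrion")

#' Glocal alignment of a query against a target sequence
#'
#' Seed-and-extend: exact k-mer seeds on both strands are chained per
#' diagonal band and each chain is extended by banded local alignment over
#' its span.  Identity is BLAST-style — identities over alignment columns,
#' gap columns included.  All alignments at or above the 80% pre-filter are
#' reported; acceptance thresholding happens downstream.
#'
#' @param query Query DNA string (>= 50 bases, no N).
#' @param target Target DNA string.
#' @param k Seed length.
#' @param min_report Pre-filter identity floor (percent).
#' @return Tibble with `q_lo`, `q_hi`, `t_lo`, `t_hi` (0-based half-open,
#'   query coordinates on the forward strand of `query`), `strand`,
#'   `identity`, `matches`, `columns`, `score`.
#' @export
align_glocal <- function(query, target, k = 15L, min_report = 80) {
  query <- toupper(query); target <- toupper(target)
  nq <- nchar(query)
  if (nq < 50) stop("query shorter than 50 bases")
  if (grepl("N", query, fixed = TRUE))
    stop("query contains N; ambiguity makes identity ill-defined")
  nt <- nchar(target)
  out <- list()
  for (s in c("+", "-")) {
    q <- if (s == "+") query else revcomp(query)
    h <- seed_hits_cpp(q, target, as.integer(k))
    if (nrow(h) == 0) next
    seeds <- tibble::tibble(a_start = h$qpos, b_start = h$tpos,
                            length = k)
    ch <- chain_seeds(seeds, key = h$tpos - h$qpos,
                      gap = max(500, 0.2 * nq))
    seen <- character(0)
    for (g in unique(ch$cluster)) {
      cg <- ch[ch$cluster == g, , drop = FALSE]
      qlo <- min(cg$a_start); qhi <- max(cg$a_start) + k
      tlo <- min(cg$b_start); thi <- max(cg$b_start) + k
      slack <- max(30L, ceiling(0.05 * nq))
      wlo <- max(0L, tlo - qlo - slack)
      whi <- min(nt, thi + (nq - qhi) + slack)
      win <- substring(target, wlo + 1L, whi)
      d <- (cg$b_start - wlo) - cg$a_start
      al <- sw_band_cpp(q, win, min(d) - slack, max(d) + slack)
      if (al$columns == 0 || al$identity < min_report) next
      t_lo <- wlo + al$b_lo; t_hi <- wlo + al$b_hi
      if (s == "+") { q_lo <- al$a_lo; q_hi <- al$a_hi }
      else { q_lo <- nq - al$a_hi; q_hi <- nq - al$a_lo }
      keyid <- paste(s, t_lo, t_hi, q_lo)
      if (keyid %in% seen) next
      seen <- c(seen, keyid)
      out[[length(out) + 1L]] <- tibble::tibble(
        q_lo = q_lo, q_hi = q_hi, t_lo = t_lo, t_hi = t_hi, strand = s,
        identity = al$identity, matches = al$matches,
        columns = al$columns, score = al$score)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(q_lo = integer(), q_hi = integer(),
                          t_lo = integer(), t_hi = integer(),
                          strand = character(), identity = numeric(),
                          matches = numeric(), columns = numeric(),
                          score = numeric()))
  dplyr::bind_rows(out) %>% dplyr::arrange(.data$t_lo)
}

# align against a contig, doubling circular contigs so parts spanning the
# arbitrary linearization origin are still seen intact
contig_alignments <- function(query, ct) {
  tseq <- if (isTRUE(ct$circular[1])) paste0(ct$seq, ct$seq) else ct$seq
  align_glocal(query, tseq)
}

# drop the duplicate second-copy hits that doubling creates; hits starting
# in the first copy are kept (their end may wrap past the contig length)
fold_circular_hits <- function(mg, ct) {
  if (!isTRUE(ct$circular[1]) || nrow(mg) == 0) return(mg)
  mg[mg$t_lo < ct$length[1], , drop = FALSE]
}

# merge collinear same-strand alignments separated by gaps of at most
# `gap_frac` of the query length; returns one row per merged group
merge_chains <- function(al, qlen, gap_frac = 0.10) {
  if (nrow(al) == 0) return(al %>% dplyr::mutate(qcov = numeric(0),
                                                 chained = logical(0)))
  gap <- gap_frac * qlen
  res <- list()
  for (s in unique(al$strand)) {
    as_ <- al[al$strand == s, , drop = FALSE]
    as_ <- as_[order(as_$t_lo), ]
    grp <- 1L; gids <- integer(nrow(as_))
    gids[1] <- grp
    for (i in seq_len(nrow(as_))[-1]) {
      prev <- as_[i - 1L, ]
      tgap <- as_$t_lo[i] - prev$t_hi
      qgap <- if (s == "+") as_$q_lo[i] - prev$q_hi else prev$q_lo - as_$q_hi[i]
      if (tgap <= gap && tgap > -50 && qgap <= gap && qgap > -50 * 2)
        gids[i] <- grp
      else { grp <- grp + 1L; gids[i] <- grp }
    }
    for (g in unique(gids)) {
      m <- as_[gids == g, , drop = FALSE]
      qcov <- 100 * interval_union_len(m$q_lo, m$q_hi) / qlen
      res[[length(res) + 1L]] <- tibble::tibble(
        t_lo = min(m$t_lo), t_hi = max(m$t_hi), strand = s,
        identity = 100 * sum(m$matches) / sum(m$columns),
        matches = sum(m$matches), columns = sum(m$columns),
        qcov = qcov, chained = nrow(m) > 1)
    }
  }
  dplyr::bind_rows(res)
}

#' Search one signature across an assembly
#'
#' Collinear same-strand chains on a contig are merged (gap at most 10% of
#' the query length) before gating, so a part split only by small indels is
#' not spuriously rejected; query coverage is the union of matched query
#' positions.  Hits pass when identity and coverage meet the gates
#' (defaults mirror stringent BLASTN screening at 98/98).  The best
#' sub-threshold evidence per contig is retained separately for
#' missing-fragment diagnosis.
#'
#' @param sig One-row tibble (`id`, `seq`) or named DNA string.
#' @param assembly Contig tibble.
#' @param min_identity,min_qcov Acceptance gates (percent).
#' @return Tibble of passing hits (`signature`, `contig`, `start`, `end`,
#'   `strand`, `identity`, `qcov`, `chained`); attribute `"diagnostics"`
#'   holds best sub-threshold evidence in the same shape.
#' @export
search_signature <- function(sig, assembly, min_identity = 98,
                             min_qcov = 98) {
  if (is.character(sig))
    sig <- tibble::tibble(id = names(sig) %||% "query", seq = sig)
  qlen <- nchar(sig$seq[1])
  hits <- list(); diag <- list()
  for (i in seq_len(nrow(assembly))) {
    ct <- assembly[i, ]
    al <- contig_alignments(sig$seq[1], ct)
    mg <- merge_chains(al, qlen)
    mg <- fold_circular_hits(mg, ct)
    if (nrow(mg) == 0) next
    mg <- mg %>%
      dplyr::mutate(signature = sig$id[1], contig = ct$id,
                    start = .data$t_lo, end = .data$t_hi) %>%
      dplyr::select("signature", "contig", "start", "end", "strand",
                    "identity", "qcov", "chained", "matches")
    pass <- mg$identity >= min_identity & mg$qcov >= min_qcov
    if (any(pass)) hits[[length(hits) + 1L]] <- mg[pass, ]
    if (any(!pass)) {
      best <- mg[!pass, ][which.max(mg$matches[!pass]), ]
      diag[[length(diag) + 1L]] <- best
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) %>%
    dplyr::select(-"matches") else empty_hits()
  attr(out, "diagnostics") <- if (length(diag))
    dplyr::bind_rows(diag) %>% dplyr::select(-"matches") else empty_hits()
  out
}

empty_hits <- function() {
  tibble::tibble(signature = character(), contig = character(),
                 start = integer(), end = integer(), strand = character(),
                 identity = numeric(), qcov = numeric(), chained = logical())
}

#' Best single hit of a genome feature
#'
#' Features (telomere, centromere, mitochondrion) are located by the single
#' highest-scoring merged chain across the whole assembly (score = matched
#' bases), with deterministic tie-breaking by contig id then start; no
#' identity or coverage gate is applied.
#'
#' @inheritParams search_signature
#' @return Zero- or one-row hit tibble.
#' @export
search_feature_best_hit <- function(sig, assembly) {
  if (is.character(sig))
    sig <- tibble::tibble(id = names(sig) %||% "feature", seq = sig)
  qlen <- nchar(sig$seq[1])
  cand <- list()
  for (i in seq_len(nrow(assembly))) {
    ct <- assembly[i, ]
    al <- contig_alignments(sig$seq[1], ct)
    mg <- merge_chains(al, qlen)
    mg <- fold_circular_hits(mg, ct)
    if (nrow(mg) == 0) next
    cand[[length(cand) + 1L]] <- mg %>%
      dplyr::mutate(signature = sig$id[1], contig = ct$id,
                    start = .data$t_lo, end = .data$t_hi)
  }
  if (length(cand) == 0) return(empty_hits())
  all <- dplyr::bind_rows(cand) %>%
    dplyr::arrange(dplyr::desc(.data$matches), .data$contig, .data$start)
  all[1, ] %>%
    dplyr::select("signature", "contig", "start", "end", "strand",
                  "identity", "qcov", "chained")
}

#' Classify a construct's assembly outcome
#'
#' Verdicts mirror the standard visual failure modes of engineered-genome
#' assemblies: `absent` (no part found), `missing_fragment` (some part has
#' no passing hit while others do — "white space"), `contig_break` (all
#' parts pass but no single contig carries them in consistent order and
#' orientation — "red line"), `complete_contiguous` otherwise.
#'
#' On circular contigs (resolved plasmid monomers) part order is checked
#' cyclically, since the linearization origin is arbitrary.
#'
#' @param parts Ordered character vector of part ids.
#' @param hits Passing-hit tibble over all signatures (from
#'   [search_signature()]).
#' @param circular_contigs Ids of contigs representing circular sequences.
#' @return One-row tibble: `verdict`, `parts_total`, `parts_passing`,
#'   `contigs` (comma-separated).
#' @export
classify_design <- function(parts, hits, circular_contigs = character(0)) {
  ph <- hits[hits$signature %in% parts, , drop = FALSE]
  found <- intersect(parts, unique(ph$signature))
  row <- function(verdict) tibble::tibble(
    verdict = verdict, parts_total = length(parts),
    parts_passing = length(found),
    contigs = paste(sort(unique(ph$contig)), collapse = ","))
  if (length(found) == 0) return(row("absent"))
  if (length(found) < length(parts)) return(row("missing_fragment"))
  # all parts pass somewhere: is there one contig with a consistent layout?
  for (ct in unique(ph$contig)) {
    hc <- ph[ph$contig == ct, , drop = FALSE]
    if (!all(parts %in% hc$signature)) next
    sel <- dplyr::bind_rows(lapply(parts, function(p) {
      hp <- hc[hc$signature == p, , drop = FALSE]
      hp[which.max(hp$identity), ]
    }))
    if (length(unique(sel$strand)) != 1) next
    if (order_consistent(sel, ct %in% circular_contigs)) {
      out <- row("complete_contiguous")
      out$contigs <- ct
      return(out)
    }
  }
  row("contig_break")
}

# do hit midpoints follow the construct's declared part order?  Linear:
# strictly monotone (direction set by strand).  Circular: the spatial order
# must be a rotation of the declared order (reversed for the minus strand).
order_consistent <- function(sel, circular) {
  n <- nrow(sel)
  if (n <= 1) return(TRUE)
  mid <- (sel$start + sel$end) / 2
  if (!circular) {
    if (sel$strand[1] == "+") return(all(diff(mid) > 0))
    return(all(diff(mid) < 0))
  }
  o <- order(mid)                       # spatial sequence of declared indices
  if (sel$strand[1] == "-") o <- rev(o)
  for (r in seq_len(n)) {
    rot <- c(o[r:n], if (r > 1) o[1:(r - 1)])
    if (all(rot == seq_len(n))) return(TRUE)
  }
  FALSE
}

#' Annotate an assembly against a signature library
#'
#' Runs the gated signature search over every part, the best-hit search
#' over genome features (telomere/centromere/mitochondrion categories),
#' classifies every construct, and builds a per-contig annotation map.
#' Contigs carrying an origin-category hit are flagged as plasmids, since
#' replication origins differentiate plasmid contigs from other small
#' contigs.
#'
#' @param assembly Contig tibble.
#' @param library List with `parts` (tibble `id`, `seq`, `category`) and
#'   optional `constructs` (tibble `construct`, `parts` comma-separated),
#'   as produced by [signature_library()] or [read_signature_library()].
#' @param min_identity,min_qcov Signature acceptance gates (percent).
#' @return Object of class `circsig_annotation`: list with `hits`,
#'   `diagnostics`, `status`, `contig_map`, `plasmid_contigs`.
#' @export
annotate_assembly <- function(assembly, library, min_identity = 98,
                              min_qcov = 98) {
  parts <- library$parts
  hits <- list(); diags <- list()
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    if (p$category %in% FEATURE_CATEGORIES) {
      h <- search_feature_best_hit(p, assembly)
      if (nrow(h) > 0) hits[[length(hits) + 1L]] <-
          h %>% dplyr::mutate(category = p$category)
    } else {
      h <- search_signature(p, assembly, min_identity, min_qcov)
      d <- attr(h, "diagnostics")
      if (nrow(h) > 0) hits[[length(hits) + 1L]] <-
          h %>% dplyr::mutate(category = p$category)
      if (nrow(d) > 0) diags[[length(diags) + 1L]] <-
          d %>% dplyr::mutate(category = p$category)
    }
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    empty_hits() %>% dplyr::mutate(category = character(0))
  diags <- if (length(diags)) dplyr::bind_rows(diags) else
    empty_hits() %>% dplyr::mutate(category = character(0))
  gated <- hits[!hits$category %in% FEATURE_CATEGORIES, , drop = FALSE]
  status <- NULL
  if (!is.null(library$constructs) && nrow(library$constructs) > 0) {
    status <- dplyr::bind_rows(lapply(seq_len(nrow(library$constructs)),
      function(i) {
        cr <- library$constructs[i, ]
        pl <- strsplit(cr$parts, ",", fixed = TRUE)[[1]]
        circ_ids <- assembly$id[!is.na(assembly$circular) & assembly$circular]
        classify_design(trimws(pl), gated, circular_contigs = circ_ids) %>%
          dplyr::mutate(construct = cr$construct, .before = 1)
      }))
  }
  contig_map <- assembly %>%
    dplyr::select("id", "length") %>%
    dplyr::left_join(hits %>% dplyr::arrange(.data$contig, .data$start),
                     by = c(id = "contig")) %>%
    dplyr::select("id", "length", "signature", "category", "start", "end",
                  "strand", "identity")
  plasmid_contigs <- sort(unique(hits$contig[hits$category == "origin"]))
  structure(list(hits = hits, diagnostics = diags, status = status,
                 contig_map = contig_map,
                 plasmid_contigs = plasmid_contigs),
            class = "circsig_annotation")
}

#' Read a signature library FASTA
#'
#' Headers carry the category as `id|category=...`; entries without a
#' category default to `other`.
#'
#' @param path FASTA path.
#' @return Tibble with `id`, `seq`, `category`.
#' @export
read_signature_library <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  ids <- names(recs)
  cat <- ifelse(grepl("\\|category=", ids),
                sub(".*\\|category=([^| ]+).*", "\\1", ids), "other")
  tibble::tibble(id = sub("\\|.*$", "", ids),
                 seq = unname(toupper(as.character(recs))), category = cat)
}

#' Write a signature library FASTA
#'
#' @param parts Tibble with `id`, `seq`, `category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_library <- function(parts, path) {
  x <- Biostrings::DNAStringSet(parts$seq)
  names(x) <- paste0(parts$id, "|category=", parts$category)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read construct definitions
#'
#' @param path TSV with columns `construct` and `parts` (comma-separated,
#'   ordered part ids).
#' @return Tibble with `construct`, `parts`.
#' @export
read_constructs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("construct", "parts") %in% names(tab)))
  tibble::as_tibble(tab[, c("construct", "parts")])
}
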