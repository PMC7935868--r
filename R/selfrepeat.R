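# Candidate-circular contig detection, tandem-monomer resolution and
# junction validation.  A collapsed plasmid contig (k concatenated copies of
# the true monomer) is recognized from its self-alignment structure, reduced
# to a consensus monomer, and confirmed circular by origin-spanning reads.

get_seq <- function(x) {
  if (is.character(x)) return(toupper(x[1]))
  stopifnot(is.data.frame(x), nrow(x) == 1, "seq" %in% names(x))
  toupper(x$seq[1])
}

#' Maximal exact matches between two sequences
#'
#' Every returned match is an exact common substring that cannot be
#' extended left or right ("maxmatch" semantics: non-unique matches are all
#' reported).  Reverse-strand matches are computed against the reverse
#' complement of `seq_b` and reported in forward coordinates of `seq_b`.
#'
#' @param seq_a,seq_b DNA strings (or one-row contig tibbles).
#' @param min_len Minimum match length (>= 8).
#' @param both_strands Also search the reverse strand of `seq_b`.
#' @return Tibble with `a_start`, `b_start` (0-based), `length`, `strand`.
#' @export
find_mems <- function(seq_a, seq_b, min_len = 20L, both_strands = FALSE) {
  stopifnot(min_len >= 4)
  a <- get_seq(seq_a); b <- get_seq(seq_b)
  fw <- tibble::as_tibble(find_mems_cpp(a, b, as.integer(min_len)))
  fw$strand <- rep("+", nrow(fw))
  if (both_strands) {
    rv <- tibble::as_tibble(find_mems_cpp(a, revcomp(b), as.integer(min_len)))
    if (nrow(rv) > 0) {
      rv$b_start <- nchar(b) - (rv$b_start + rv$length)
      rv$strand <- "-"
    } else rv$strand <- character(0)
    fw <- dplyr::bind_rows(fw, rv)
  }
  dplyr::arrange(fw, .data$a_start, .data$b_start)
}

# greedy collinear chaining of MEM seeds into clusters: seeds join while
# their diagonal drifts by at most drift_frac of the running span and the
# positional gap stays within `gap`
chain_seeds <- function(seeds, key, gap = 500, drift_frac = 0.10) {
  if (nrow(seeds) == 0) return(seeds[0, ])
  o <- order(key, seeds$a_start)
  seeds <- seeds[o, ]; key <- key[o]
  n <- nrow(seeds)
  cl <- integer(n)
  cur <- 0L; ref_key <- 0; cl_start <- 0; cl_end <- -Inf
  for (i in seq_len(n)) {
    new_cluster <- cur == 0L
    if (!new_cluster) {
      span <- max(cl_end, seeds$a_start[i] + seeds$length[i]) - cl_start
      tol <- max(50, drift_frac * span)
      if (abs(key[i] - ref_key) > tol ||
          seeds$a_start[i] - cl_end > gap ||
          seeds$a_start[i] < cl_start - gap)   # no jumping back to a new region
        new_cluster <- TRUE
    }
    if (new_cluster) {
      cur <- cur + 1L
      ref_key <- key[i]
      cl_start <- seeds$a_start[i]
      cl_end <- seeds$a_start[i] + seeds$length[i]
    } else {
      cl_end <- max(cl_end, seeds$a_start[i] + seeds$length[i])
    }
    cl[i] <- cur
  }
  seeds$cluster <- cl
  seeds
}

#' Self-repeat clusters of a contig
#'
#' Maximal exact matches of the contig against itself (both strands, the
#' trivial main-diagonal match removed) are chained into collinear clusters;
#' clusters shorter than `mincluster`/`min_len` or below `min_id` estimated
#' identity are discarded.  Identity is estimated as matched bases over the
#' chained span.  `seed_min` is the exact-match seed floor; the headline
#' `min_len`/`min_id` thresholds filter reported clusters, mirroring how
#' whole-genome aligners filter reported alignments rather than seeds.
#'
#' @param contig DNA string or one-row contig tibble.
#' @param min_len,mincluster Minimum reported cluster span, bases.
#' @param min_id Minimum estimated identity (percent).
#' @param seed_min Minimum exact seed length.
#' @return Tibble of clusters: spans on both copies, strand, `n_seeds`,
#'   `matched`, `total_len`, `est_identity`, `offset`.
#' @export
self_repeat_clusters <- function(contig, min_len = 2000L, mincluster = 2000L,
                                 min_id = 99, seed_min = 24L) {
  seq <- get_seq(contig)
  m <- find_mems(seq, seq, min_len = seed_min, both_strands = TRUE)
  m <- m %>%
    dplyr::filter(!(.data$strand == "+" & .data$a_start == .data$b_start),
                  .data$a_start <= .data$b_start)
  if (nrow(m) == 0) return(empty_clusters())
  res <- list()
  for (s in unique(m$strand)) {
    ms <- m[m$strand == s, , drop = FALSE]
    key <- if (s == "+") ms$b_start - ms$a_start else ms$b_start + ms$a_start
    ch <- chain_seeds(ms, key)
    cc <- ch %>%
      dplyr::group_by(.data$cluster) %>%
      dplyr::summarise(
        n_seeds = dplyr::n(),
        a_end = max(.data$a_start + .data$length),
        b_end = max(.data$b_start + .data$length),
        a_start = min(.data$a_start),
        b_start = min(.data$b_start),
        matched = sum(.data$length), .groups = "drop") %>%
      dplyr::mutate(strand = s) %>%
      dplyr::select("cluster", "n_seeds", "a_start", "a_end", "b_start",
                    "b_end", "matched", "strand")
    res[[s]] <- cc
  }
  out <- dplyr::bind_rows(res) %>%
    dplyr::mutate(total_len = .data$a_end - .data$a_start,
                  offset = .data$b_start - .data$a_start) %>%
    dplyr::filter(.data$total_len >= max(min_len, mincluster))
  if (nrow(out) == 0) return(empty_clusters())
  # identity of the chained spans by banded alignment (seed-matched bases
  # over the span would understate it: every mismatch also truncates the
  # flanking exact matches below the seed floor)
  out$est_identity <- vapply(seq_len(nrow(out)), function(i) {
    cluster_identity(seq, out[i, ])
  }, numeric(1))
  out %>%
    dplyr::filter(.data$est_identity >= min_id) %>%
    dplyr::select(-"cluster") %>%
    dplyr::arrange(dplyr::desc(.data$total_len))
}

# alignment identity between the two spans of a self-repeat cluster,
# sampled to the leading 12 kb for very long spans
cluster_identity <- function(seq, cl, cap = 12000L) {
  a <- substring(seq, cl$a_start + 1, cl$a_end)
  b <- substring(seq, cl$b_start + 1, cl$b_end)
  if (cl$strand == "-") b <- revcomp(b)
  if (nchar(a) > cap) a <- substring(a, 1, cap)
  if (nchar(b) > cap) b <- substring(b, 1, cap)
  slack <- max(60L, ceiling(0.02 * max(nchar(a), nchar(b))))
  nw_identity(a, b, slack = slack)$identity
}

empty_clusters <- function() {
  tibble::tibble(n_seeds = integer(), a_start = integer(), a_end = integer(),
                 b_start = integer(), b_end = integer(), matched = integer(),
                 strand = character(), total_len = integer(),
                 est_identity = numeric(), offset = integer())
}

#' Is a contig a candidate circular sequence?
#'
#' A contig is a candidate if the assembler flagged it circular, or if it is
#' shorter than `max_len` (default 50 kb) and its self-repeat clusters cover
#' at least `min_fraction` of its length — the signature of a circular
#' plasmid collapsed into a tandem multimer.
#'
#' @param contig One-row contig tibble (or DNA string).
#' @param metadata Optional assembler metadata tibble (`id`, `circular`).
#' @param max_len Length gate for the repeat route, bases.
#' @param min_fraction Minimum self-repeat span coverage of the contig.
#' @param ... Passed to [self_repeat_clusters()].
#' @return List with `candidate` (logical) and `reason` (`"flagged"`,
#'   `"repetitive"`, or `"no"`).
#' @export
is_candidate_circular <- function(contig, metadata = NULL, max_len = 50000L,
                                  min_fraction = 0.5, ...) {
  flagged <- FALSE
  if (is.data.frame(contig) && !is.null(metadata) && "id" %in% names(contig)) {
    row <- metadata[metadata$id == contig$id[1], ]
    if (nrow(row) == 1 && isTRUE(row$circular)) flagged <- TRUE
  }
  if (!flagged && is.data.frame(contig) && isTRUE(contig$circular[1]))
    flagged <- TRUE
  if (flagged) return(list(candidate = TRUE, reason = "flagged"))
  seq <- get_seq(contig)
  L <- nchar(seq)
  if (L >= max_len) return(list(candidate = FALSE, reason = "no"))
  cl <- self_repeat_clusters(seq, ...)
  if (nrow(cl) > 0) {
    cov <- interval_union_len(cl$a_start, cl$a_end) / L
    if (cov >= min_fraction)
      return(list(candidate = TRUE, reason = "repetitive"))
  }
  list(candidate = FALSE, reason = "no")
}

#' Detect the tandem period of a collapsed contig
#'
#' Candidate periods are taken from the match-length-weighted histogram of
#' self-match offsets; each candidate is validated by aligning the leading
#' period-length window against every subsequent window.  The smallest
#' period whose mean window identity reaches `min_identity` (and whose copy
#' count is at least `min_copies`) is accepted.
#'
#' @param contig DNA string or one-row contig tibble.
#' @param min_period Smallest admissible period, bases.
#' @param min_identity Window-validation identity floor (percent).  Set
#'   below the cluster-detection identity gate on purpose: consensus
#'   building downstream corrects noise that would fail a 99% gate.
#' @param min_copies Minimum copy count (contig length / period).
#' @param seed_min Exact seed floor for the offset histogram.
#' @return List with `period`, `copies`, `monomer_identity`, or `NULL` when
#'   no period qualifies.
#' @export
detect_tandem_period <- function(contig, min_period = 500L, min_identity = 95,
                                 min_copies = 1.5, seed_min = 24L) {
  seq <- get_seq(contig)
  L <- nchar(seq)
  if (L < 2 * min_period) return(NULL)
  m <- find_mems(seq, seq, min_len = seed_min, both_strands = FALSE) %>%
    dplyr::filter(.data$b_start > .data$a_start) %>%
    dplyr::mutate(offset = .data$b_start - .data$a_start) %>%
    dplyr::filter(.data$offset >= min_period,
                  .data$offset <= L / min_copies)
  if (nrow(m) == 0) return(NULL)
  mass <- m %>%
    dplyr::group_by(.data$offset) %>%
    dplyr::summarise(mass = sum(.data$length), .groups = "drop") %>%
    dplyr::arrange(.data$offset)
  # cluster nearby offsets (2% relative tolerance)
  grp <- cumsum(c(1, diff(mass$offset) > pmax(20, 0.02 * mass$offset[-1])))
  cand <- mass %>%
    dplyr::mutate(grp = grp) %>%
    dplyr::group_by(.data$grp) %>%
    dplyr::summarise(period = .data$offset[which.max(.data$mass)],
                     mass = sum(.data$mass), .groups = "drop") %>%
    dplyr::filter(.data$mass >= 0.05 * sum(.data$mass)) %>%
    dplyr::arrange(.data$period)
  for (P in cand$period) {
    v <- validate_period(seq, P, min_identity)
    if (!is.null(v)) {
      # a window that is itself tandem-repetitive below the period floor is
      # a microsatellite, not a collapsed plasmid monomer
      if (has_subperiod(substring(seq, 1, P), min_period)) return(NULL)
      return(list(period = as.integer(P), copies = L / P,
                  monomer_identity = v))
    }
  }
  NULL
}

has_subperiod <- function(window, min_period, min_match = 0.95) {
  v <- utf8ToInt(window)
  P <- length(v)
  for (q in seq_len(min(min_period - 1L, P %/% 2L))) {
    if (mean(v[1:(P - q)] == v[(q + 1):P]) >= min_match) return(TRUE)
  }
  FALSE
}

validate_period <- function(seq, P, min_identity) {
  L <- nchar(seq)
  nwin <- L %/% P
  if (L / P < 1.5) return(NULL)
  prefix <- substring(seq, 1, P)
  slack <- max(30L, ceiling(0.03 * P))
  ids <- c()
  for (i in seq_len(nwin - 1)) {
    win <- substring(seq, i * P + 1, (i + 1) * P)
    ids <- c(ids, nw_identity(prefix, win, slack = slack)$identity)
  }
  tail_len <- L - nwin * P
  if (tail_len >= min(200, 0.2 * P)) {
    win <- substring(seq, nwin * P + 1, L)
    ids <- c(ids, nw_identity(substring(prefix, 1, tail_len), win,
                              slack = slack)$identity)
  }
  if (length(ids) == 0) return(NULL)
  if (mean(ids) >= min_identity) mean(ids) else NULL
}

#' Collapse a tandem contig to its consensus circular monomer
#'
#' The contig's `floor(copies)` period-length windows are pairwise aligned
#' to the first window and a column-wise majority-vote consensus is taken
#' (isolated per-copy errors are outvoted).  The consensus is reported in
#' canonical form: the lexicographic minimum over rotations of both
#' strands, so the result is independent of the collapse's arbitrary
#' origin and orientation.
#'
#' @param contig DNA string or one-row contig tibble.
#' @param period Period from [detect_tandem_period()].
#' @return List with `monomer` (canonical sequence), `period`, `windows`
#'   used.
#' @export
monomerize <- function(contig, period) {
  seq <- get_seq(contig)
  L <- nchar(seq)
  P <- as.integer(period)
  stopifnot(P >= 1, P <= L)
  nwin <- L %/% P
  w0 <- substring(seq, 1, P)
  if (nwin < 2) {
    warning("fewer than 2 full windows; returning first window unpolished")
    return(list(monomer = canonical_rotation(w0), period = P, windows = 1L))
  }
  slack <- max(30L, ceiling(0.03 * P))
  # votes[p] collects the aligned character of each window at w0 position p
  votes <- vector("list", nwin)
  votes[[1]] <- strsplit(w0, "", fixed = TRUE)[[1]]
  inserts <- list()
  for (i in seq_len(nwin - 1)) {
    win <- substring(seq, i * P + 1, (i + 1) * P)
    al <- nw_band_cpp(w0, win, -slack, slack, keep_align = TRUE)
    a <- strsplit(al$a_aligned, "", fixed = TRUE)[[1]]
    b <- strsplit(al$b_aligned, "", fixed = TRUE)[[1]]
    v <- character(P); vi <- 0L
    pending <- character(0)
    for (j in seq_along(a)) {
      if (a[j] == "-") {              # insertion in this window
        pending <- c(pending, b[j])
      } else {
        vi <- vi + 1L
        v[vi] <- b[j]
        if (length(pending) > 0) {
          key <- as.character(vi - 1L)
          inserts[[key]] <- c(inserts[[key]], paste(pending, collapse = ""))
          pending <- character(0)
        }
      }
    }
    votes[[i + 1]] <- v
  }
  vm <- do.call(rbind, votes)          # nwin x P character matrix
  cons <- apply(vm, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  out <- character(0)
  for (p in seq_len(P)) {
    key <- as.character(p - 1L)
    if (!is.null(inserts[[key]])) {
      tb <- sort(table(inserts[[key]]), decreasing = TRUE)
      if (tb[1] > nwin / 2) out <- c(out, names(tb)[1])
    }
    if (cons[p] != "-") out <- c(out, cons[p])
  }
  list(monomer = canonical_rotation(paste(out, collapse = "")), period = P,
       windows = nwin)
}

#' Count reads spanning a circular monomer's origin
#'
#' Reads are matched against the doubled monomer; a read supports
#' circularity when a collinear chain of exact seeds crosses the canonical
#' origin with at least `anchor` seed-supported bases on each side.
#'
#' @param monomer_seq Monomer DNA string (length > 2 * `anchor`).
#' @param long_reads Read tibble.
#' @param anchor Required flank on each side of the origin, bases.
#' @param k Exact seed length.
#' @param max_gap Maximum gap between chained seeds, bases.
#' @return Integer junction support (number of spanning reads).
#' @export
validate_junction <- function(monomer_seq, long_reads, anchor = 500L,
                              k = 15L, max_gap = 300L) {
  seq <- get_seq(monomer_seq)
  L <- nchar(seq)
  stopifnot(L > 2 * anchor)
  if (is.null(long_reads) || nrow(long_reads) == 0) return(0L)
  D <- paste0(seq, seq)
  region <- substring(D, L - anchor - 100 + 1, L + anchor + 100)
  hit <- kmer_region_filter_cpp(long_reads$seq, region, as.integer(k))
  cand <- long_reads$seq[hit]
  support <- 0L
  for (rs in cand) {
    if (read_spans_junction(rs, D, L, anchor, k, max_gap) ||
        read_spans_junction(revcomp(rs), D, L, anchor, k, max_gap))
      support <- support + 1L
  }
  support
}

read_spans_junction <- function(read, D, L, anchor, k, max_gap) {
  h <- seed_hits_cpp(read, D, as.integer(k))
  if (nrow(h) == 0) return(FALSE)
  h <- h[h$tpos >= L - anchor - 2000 & h$tpos <= L + anchor + 2000, ,
         drop = FALSE]
  if (nrow(h) == 0) return(FALSE)
  h$diag <- h$tpos - h$qpos
  h <- h[order(h$diag, h$tpos), ]
  grp <- cumsum(c(1, diff(h$diag) > 200))
  for (g in unique(grp)) {
    hg <- h[grp == g, , drop = FALSE]
    hg <- hg[order(hg$tpos), ]
    runs <- cumsum(c(1, diff(hg$tpos) > max_gap))
    for (r in unique(runs)) {
      hr <- hg[runs == r, , drop = FALSE]
      if (min(hr$tpos) <= L - anchor && max(hr$tpos) + k >= L + anchor)
        return(TRUE)
    }
  }
  FALSE
}

#' Resolve circular contigs in an assembly
#'
#' Routes each contig through the candidate gate (assembler circular flag,
#' or short + self-repetitive), detects and collapses tandem structure to a
#' consensus monomer, and (when reads are given) counts origin-spanning
#' reads.  The consensus monomer is always preferred over the original
#' contig; originals are recorded in the decision table.
#'
#' @param contigs Contig tibble.
#' @param metadata Optional assembler metadata tibble.
#' @param long_reads Optional read tibble for junction validation.
#' @param max_len,min_fraction Candidate gate, see [is_candidate_circular()].
#' @param min_period Smallest admissible tandem period.
#' @return List of class `circsig_resolution`: `resolved` (monomer contig
#'   tibble with `period`, `copies`, `support`, `source_id`), `linear`
#'   (untouched contigs), `decisions` (per-contig table).
#' @export
resolve_circular <- function(contigs, metadata = NULL, long_reads = NULL,
                             max_len = 50000L, min_fraction = 0.5,
                             min_period = 500L) {
  resolved <- list(); linear <- list(); dec <- list()
  for (i in seq_len(nrow(contigs))) {
    ct <- contigs[i, ]
    cand <- is_candidate_circular(ct, metadata, max_len = max_len,
                                  min_fraction = min_fraction)
    row <- tibble::tibble(id = ct$id, length = ct$length,
                          candidate = cand$candidate, reason = cand$reason,
                          period = NA_integer_, copies = NA_real_,
                          monomer_identity = NA_real_,
                          junction_support = NA_integer_,
                          action = "kept_linear")
    if (!cand$candidate) {
      linear[[length(linear) + 1L]] <- ct
      dec[[length(dec) + 1L]] <- row
      next
    }
    tp <- detect_tandem_period(ct, min_period = min_period)
    if (!is.null(tp)) {
      mono <- monomerize(ct, tp$period)$monomer
      row$period <- tp$period; row$copies <- tp$copies
      row$monomer_identity <- tp$monomer_identity
      row$action <- "monomerized"
    } else {
      mono <- canonical_rotation(ct$seq)
      row$period <- ct$length; row$copies <- 1
      row$action <- "kept_circular"
    }
    supp <- NA_integer_
    if (!is.null(long_reads) && nchar(mono) > 2 * 500)
      supp <- validate_junction(mono, long_reads)
    row$junction_support <- supp
    resolved[[length(resolved) + 1L]] <-
      as_contigs(ct$id, mono, depth = ct$depth, circular = TRUE) %>%
      dplyr::mutate(period = row$period, copies = row$copies,
                    support = supp, source_id = ct$id)
    dec[[length(dec) + 1L]] <- row
  }
  structure(list(resolved = dplyr::bind_rows(resolved),
                 linear = dplyr::bind_rows(linear),
                 decisions = dplyr::bind_rows(dec)),
            class = "circsig_resolution")
}
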