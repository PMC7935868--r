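# Read-depth profiling and copy-number estimation.  Depth comes either
# from the built-in minimizer-vote mapper (each read assigned once, to its
# best collinear chain) or from precomputed PAF alignments.

#' Build per-base depth profiles
#'
#' Exactly one of `reads` or `paf` must be given.  With reads, each read is
#' assigned to its best target location by minimizer-seed voting plus best
#' collinear chain; per-base depth is incremented over the chained span
#' projected to full read length.  Reads with fewer than `min_seeds`
#' supporting seeds stay unassigned.  Circular targets are mapped against
#' their doubled sequence with depth folded modulo length, so
#' origin-wrapping reads are counted correctly.
#'
#' @param targets Contig tibble (`id`, `seq`, optional `circular`).
#' @param reads Read tibble, any platform.
#' @param paf PAF tibble from [read_paf()] or a PAF file path.
#' @param k,w Minimizer seed length and window.
#' @param min_seeds Minimum supporting seeds per assigned read.
#' @return Object of class `circsig_depth`: list with `profiles` (named
#'   list of integer vectors), `assignments` (per-read tibble), `source`.
#' @export
build_depth <- function(targets, reads = NULL, paf = NULL, k = 15L, w = 10L,
                        min_seeds = 3L) {
  if (!is.null(reads) && !is.null(paf))
    stop("give either reads or paf, not both (ambiguous depth source)")
  if (is.null(reads) && is.null(paf))
    stop("one of reads or paf is required")
  circ <- targets$circular
  if (is.null(circ)) circ <- rep(FALSE, nrow(targets))
  circ[is.na(circ)] <- FALSE
  if (!is.null(reads)) {
    res <- map_reads_cpp(targets$seq, circ, reads$seq, as.integer(k),
                         as.integer(w), as.integer(min_seeds))
    profiles <- stats::setNames(res$depth, targets$id)
    asg <- tibble::as_tibble(res$reads) %>%
      dplyr::mutate(read = reads$id,
                    target = targets$id[.data$target], .before = 1)
    src <- if (all(reads$platform == "long")) "long" else "short"
    return(structure(list(profiles = profiles, assignments = asg,
                          source = src), class = "circsig_depth"))
  }
  if (is.character(paf)) paf <- read_paf(paf)
  profiles <- lapply(seq_len(nrow(targets)), function(i) {
    L <- targets$length[i]
    d <- integer(L + 1L)
    rows <- paf[paf$tname == targets$id[i], , drop = FALSE]
    if (nrow(rows) > 0) {
      st <- pmax(rows$tstart, 0L); en <- pmin(rows$tend, L)
      for (j in seq_along(st)) {
        if (en[j] > st[j]) {
          d[st[j] + 1L] <- d[st[j] + 1L] + 1L
          d[en[j] + 1L] <- d[en[j] + 1L] - 1L
        }
      }
    }
    cumsum(d)[seq_len(L)]
  })
  structure(list(profiles = stats::setNames(profiles, targets$id),
                 assignments = NULL, source = "paf"),
            class = "circsig_depth")
}

#' Read a PAF alignment file
#'
#' Standard minimap2-style columns 1-12.
#'
#' @param path PAF path.
#' @return Tibble with `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 12)
  tab <- tab[, 1:12]
  names(tab) <- cols
  tibble::as_tibble(tab)
}

#' Export depth profiles as a long table
#'
#' @param depth A `circsig_depth` object.
#' @return Tibble with `contig`, `pos` (0-based), `depth`.
#' @export
depth_table <- function(depth) {
  dplyr::bind_rows(lapply(names(depth$profiles), function(id)
    tibble::tibble(contig = id,
                   pos = seq_along(depth$profiles[[id]]) - 1L,
                   depth = depth$profiles[[id]])))
}

as_interval <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(contig = x$contig[1], start = x$start[1], end = x$end[1])
  } else {
    stopifnot(all(c("contig", "start", "end") %in% names(x)))
    x
  }
}

mean_depth_over <- function(depth, iv) {
  prof <- depth$profiles[[iv$contig]]
  if (is.null(prof)) stop("no depth profile for contig ", iv$contig)
  mean(prof[(iv$start + 1L):iv$end])
}

#' Copy number as a locus depth ratio
#'
#' Mean per-base depth over the target locus divided by mean depth over a
#' single-copy reference locus (for example a selection marker versus the
#' ACT1 locus).  Mean depth is used rather than read counts because the
#' two loci generally differ in length.
#'
#' @param depth A `circsig_depth` object.
#' @param target,reference Intervals: one-row tibbles or lists with
#'   `contig`, `start`, `end` (0-based half-open).
#' @return Object of class `circsig_cn`.
#' @export
locus_copy_ratio <- function(depth, target, reference) {
  ti <- as_interval(target); ri <- as_interval(reference)
  td <- mean_depth_over(depth, ti)
  rd <- mean_depth_over(depth, ri)
  if (rd <= 0) stop("single-copy reference not covered")
  structure(list(target = ti$contig, target_depth = td,
                 reference = ri$contig, reference_depth = rd,
                 ratio = td / rd, method = "locus_ratio"),
            class = "circsig_cn")
}

#' Tandem-repeat copies present in an assembly
#'
#' Total assembly bases covered by passing unit alignments (glocal search,
#' identity at least `min_identity`, merged) divided by the unit length.
#'
#' @param assembly Contig tibble.
#' @param unit_seq Repeat unit (>= 200 bases).
#' @param min_identity Identity floor for counted alignments (percent).
#' @param min_len Minimum alignment span counted, bases; excludes chance
#'   micro-alignments that are not repeat copies.
#' @return Object of class `circsig_cn` (method `assembly_tiling`).
#' @export
repeat_copies_from_assembly <- function(assembly, unit_seq,
                                        min_identity = 90, min_len = 100L) {
  stopifnot(nchar(unit_seq) >= 200)
  covered <- 0
  for (i in seq_len(nrow(assembly))) {
    al <- align_glocal(unit_seq, assembly$seq[i])
    al <- al[al$identity >= min_identity &
               (al$t_hi - al$t_lo) >= min_len, , drop = FALSE]
    if (nrow(al) > 0)
      covered <- covered + interval_union_len(al$t_lo, al$t_hi)
  }
  structure(list(target = "repeat_unit", target_depth = NA_real_,
                 reference = "assembly", reference_depth = NA_real_,
                 ratio = covered / nchar(unit_seq),
                 method = "assembly_tiling"),
            class = "circsig_cn")
}

#' Tandem-repeat copies estimated from raw reads
#'
#' Read base mass assigned to the repeat unit divided by unit length times
#' genome mean depth.  Because tandem-array reads cross unit boundaries,
#' reads are mapped against a multi-copy concatenation of the unit and the
#' assigned mass is measured on the read side of the chain.
#'
#' @param reads Read tibble.
#' @param unit_seq Repeat unit (>= 200 bases).
#' @param genome_mean_depth Single-copy genome depth (x); must be > 0.
#' @param k,w Mapper seed parameters.
#' @return Object of class `circsig_cn` (method `read_mass`).
#' @export
repeat_copies_from_reads <- function(reads, unit_seq, genome_mean_depth,
                                     k = 15L, w = 10L) {
  if (genome_mean_depth <= 0) stop("genome_mean_depth must be > 0")
  ul <- nchar(unit_seq)
  m <- min(24L, max(3L, ceiling(max(nchar(reads$seq)) / ul) + 2L))
  target <- as_contigs("unit_array", strrep(unit_seq, m))
  dp <- build_depth(target, reads = reads, k = k, w = w)
  mass <- sum(dp$assignments$qbases[!is.na(dp$assignments$target)])
  structure(list(target = "repeat_unit", target_depth = NA_real_,
                 reference = "genome", reference_depth = genome_mean_depth,
                 ratio = mass / (ul * genome_mean_depth),
                 method = "read_mass"),
            class = "circsig_cn")
}

#' Detect hemizygous (half-depth) regions
#'
#' Windowed median depth is compared with the median of the flanking 10
#' windows on each side; at least `min_windows` consecutive windows whose
#' ratio falls in `band` (default 0.35-0.65, separating a 0.5x hemizygous
#' dip from both noise and homozygous zero-depth deletions) are merged and
#' reported.
#'
#' @param profile Integer depth vector (or a `circsig_depth` plus `contig`).
#' @param contig Contig id when `profile` is a `circsig_depth`.
#' @param window Window size, bases.
#' @param band Accepted depth-ratio band.
#' @param min_windows Minimum consecutive flagged windows.
#' @param edge_windows Windows excluded at each contig end, where linear
#'   coverage ramps down for purely geometric reasons and would mimic a
#'   half-depth dip.
#' @return Tibble with `start`, `end` (0-based half-open), `n_windows`,
#'   `mean_ratio`.
#' @export
detect_hemizygous <- function(profile, contig = NULL, window = 1000L,
                              band = c(0.35, 0.65), min_windows = 2L,
                              edge_windows = 3L) {
  if (inherits(profile, "circsig_depth")) {
    stopifnot(!is.null(contig))
    profile <- profile$profiles[[contig]]
  }
  L <- length(profile)
  nw <- L %/% window
  if (nw < 5) stop("contig shorter than 5 windows")
  wm <- vapply(seq_len(nw), function(i)
    stats::median(profile[((i - 1L) * window + 1L):(i * window)]),
    numeric(1))
  ratio <- vapply(seq_len(nw), function(i) {
    idx <- setdiff(max(1L, i - 10L):min(nw, i + 10L), i)
    fl <- stats::median(wm[idx])
    if (fl <= 0) return(NA_real_)
    wm[i] / fl
  }, numeric(1))
  flagged <- !is.na(ratio) & ratio >= band[1] & ratio <= band[2]
  if (edge_windows > 0) {
    ew <- seq_len(min(edge_windows, nw))
    flagged[ew] <- FALSE
    flagged[nw + 1L - ew] <- FALSE
  }
  out <- list()
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= min_windows) {
      i0 <- starts[j]; i1 <- ends[j]
      out[[length(out) + 1L]] <- tibble::tibble(
        start = (i0 - 1L) * window, end = i1 * window,
        n_windows = i1 - i0 + 1L,
        mean_ratio = mean(ratio[i0:i1]))
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          n_windows = integer(), mean_ratio = numeric()))
  dplyr::bind_rows(out)
}
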