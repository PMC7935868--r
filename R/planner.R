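# Sequencing-design arithmetic: coverage, dilution and multiplexing.

#' Parse a base-pair quantity
#'
#' Accepts numbers (bases) or strings with bp/kb/Mb/Gb suffixes, e.g.
#' `"12.1 Mb"`.
#'
#' @param x Numeric or character scalar/vector.
#' @return Numeric bases.
#' @export
parse_bp <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*([KkMmGg]?)[Bb]?[Pp]?\\s*$", x))
  vapply(seq_along(x), function(i) {
    mm <- m[[i]]
    if (length(mm) == 0) stop("cannot parse base-pair quantity: ", x[i])
    mult <- switch(toupper(mm[3]), K = 1e3, M = 1e6, G = 1e9, 1)
    as.numeric(mm[2]) * mult
  }, numeric(1))
}

#' Bases needed for a coverage target
#'
#' @param genome_size Genome size (bases, or a string like `"12.1 Mb"`).
#' @param coverage Depth (x).
#' @return Exact bases (numeric integer value).
#' @export
coverage_bp <- function(genome_size, coverage) {
  g <- parse_bp(genome_size)
  if (any(g <= 0) || any(coverage <= 0))
    stop("genome size and coverage must be positive")
  round(g * coverage)
}

#' Background bases for a spike-in dilution
#'
#' @param focal_bp Focal read bases (or string).
#' @param ratio Background:focal ratio (>= 0).
#' @return Background bases.
#' @export
dilution_background_bp <- function(focal_bp, ratio) {
  if (any(ratio < 0)) stop("ratio must be >= 0")
  round(parse_bp(focal_bp) * ratio)
}

#' Genomes that fit on one flow cell
#'
#' Floor of flow-cell yield over per-genome requirement: a fractional
#' genome cannot be sequenced.
#'
#' @param flowcell_yield_bp Yield (bases or string).
#' @param per_genome_bp Requirement per genome (bases or string).
#' @return Integer genome count.
#' @export
multiplex_capacity <- function(flowcell_yield_bp, per_genome_bp) {
  y <- parse_bp(flowcell_yield_bp); p <- parse_bp(per_genome_bp)
  if (any(y <= 0) || any(p <= 0)) stop("inputs must be positive")
  as.integer(y %/% p)
}

#' Plan a dilution series
#'
#' @param focal_bp Focal read bases.
#' @param ratios Background:focal ratios.
#' @return Tibble with `ratio`, `focal_bp`, `background_bp`.
#' @export
plan_dilution_series <- function(focal_bp, ratios = c(1, 10, 100, 1000)) {
  f <- parse_bp(focal_bp)
  tibble::tibble(ratio = ratios, focal_bp = f,
                 background_bp = dilution_background_bp(f, ratios))
}
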