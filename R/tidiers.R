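# broom-style tidiers and print methods for result objects.

#' @export
tidy.circsig_cn <- function(x, ...) {
  tibble::tibble(target = x$target, target_depth = x$target_depth,
                 reference = x$reference,
                 reference_depth = x$reference_depth, ratio = x$ratio,
                 method = x$method)
}

#' @export
glance.circsig_cn <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, method = x$method)
}

#' @export
print.circsig_cn <- function(x, ...) {
  cat(sprintf("<copy number estimate> method=%s ratio=%.3f\n",
              x$method, x$ratio))
  invisible(x)
}

#' @export
tidy.circsig_t2t <- function(x, ...) x$chromosomes

#' @export
glance.circsig_t2t <- function(x, ...) {
  tibble::tibble(n_chromosomes = nrow(x$chromosomes),
                 n_complete = sum(x$chromosomes$complete),
                 percent_complete = x$percent_complete)
}

#' @export
print.circsig_t2t <- function(x, ...) {
  cat(sprintf("<T2T completeness> %d/%d chromosomes complete (%.1f%%)\n",
              sum(x$chromosomes$complete), nrow(x$chromosomes),
              x$percent_complete))
  print(x$chromosomes)
  invisible(x)
}

#' @export
tidy.circsig_annotation <- function(x, ...) x$hits

#' @export
glance.circsig_annotation <- function(x, ...) {
  v <- if (is.null(x$status)) character(0) else x$status$verdict
  tibble::tibble(n_hits = nrow(x$hits),
                 n_constructs = length(v),
                 n_complete_contiguous = sum(v == "complete_contiguous"),
                 n_plasmid_contigs = length(x$plasmid_contigs))
}

#' @export
print.circsig_annotation <- function(x, ...) {
  cat(sprintf("<assembly annotation> %d hits", nrow(x$hits)))
  if (!is.null(x$status))
    cat(sprintf(", %d constructs (%d complete_contiguous)",
                nrow(x$status),
                sum(x$status$verdict == "complete_contiguous")))
  cat(sprintf(", plasmid contigs: %s\n",
              if (length(x$plasmid_contigs)) paste(x$plasmid_contigs,
                                                   collapse = ", ")
              else "none"))
  if (!is.null(x$status)) print(x$status)
  invisible(x)
}

#' @export
tidy.circsig_resolution <- function(x, ...) x$decisions

#' @export
glance.circsig_resolution <- function(x, ...) {
  tibble::tibble(n_resolved = nrow(x$resolved), n_linear = nrow(x$linear))
}

#' @export
print.circsig_resolution <- function(x, ...) {
  cat(sprintf("<circular resolution> %d resolved, %d kept linear\n",
              nrow(x$resolved), nrow(x$linear)))
  print(x$decisions)
  invisible(x)
}
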