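# End-to-end workflow: classify candidate circulars, resolve monomers,
# merge with linear contigs, annotate, estimate copy number, report.

write_tsv_q <- function(x, path) readr::write_tsv(x, path, progress = FALSE)

#' Run the full resolution + annotation workflow
#'
#' Stage order: candidate classification and circular resolution; merge of
#' resolved circular monomers with linear contigs into the final assembly;
#' signature annotation and construct classification; per-contig copy
#' number from read depth (when reads are given); telomere-to-telomere
#' completeness (when a reference is given).  Every stage writes its
#' outputs under `out_dir`; a stage failure aborts with the stage name,
#' preserving earlier outputs.
#'
#' @param contigs Assembly contig tibble (or FASTA path).
#' @param metadata Optional assembler metadata tibble (or TSV path).
#' @param long_reads Optional long-read tibble (or FASTQ path).
#' @param short_reads Optional short-read tibble; used for depth when no
#'   long reads are given.
#' @param library Optional signature library list (`parts`, `constructs`).
#' @param reference Optional reference chromosome tibble for completeness.
#' @param features Optional feature tibble for completeness.
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding thresholds: `min_identity`,
#'   `min_qcov` (annotation gates, default 98/98), `max_len` (candidate
#'   length gate, default 50000), `min_period`, `min_fraction`,
#'   `t2t_min_frac`; set `copy_number = FALSE` to skip depth profiling.
#' @return Invisibly, a list with `assembly`, `resolution`, `annotation`,
#'   `copy_number`, `t2t`, and output paths.
#' @export
run_pipeline <- function(contigs, metadata = NULL, long_reads = NULL,
                         short_reads = NULL, library = NULL,
                         reference = NULL, features = NULL,
                         out_dir = "circsig_out", config = list()) {
  cfg <- utils::modifyList(list(min_identity = 98, min_qcov = 98,
                                max_len = 50000L, min_fraction = 0.5,
                                min_period = 500L, t2t_min_frac = 0.95),
                           config)
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (is.character(metadata)) metadata <- read_assembly_metadata(metadata)
  if (is.character(long_reads)) long_reads <- read_fastq(long_reads, "long")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|",
                               ..., "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logline("start:", nrow(contigs), "contigs,",
          if (is.null(long_reads)) 0 else nrow(long_reads), "long reads")

  res <- stage("resolve_circular", resolve_circular(
    contigs, metadata, long_reads, max_len = cfg$max_len,
    min_fraction = cfg$min_fraction, min_period = cfg$min_period))
  resolved <- res$resolved
  if (nrow(resolved) > 0) {
    hdr <- resolved %>%
      dplyr::mutate(id = sprintf("%s period=%d copies=%.2f support=%s",
                                 .data$id, .data$period, .data$copies,
                                 ifelse(is.na(.data$support), "NA",
                                        .data$support)))
    write_fasta(hdr, file.path(out_dir, "resolved_circular.fasta"))
  } else {
    writeLines(character(0), file.path(out_dir, "resolved_circular.fasta"))
  }
  if (nrow(res$linear) > 0)
    write_fasta(res$linear, file.path(out_dir, "linear.fasta"))
  write_tsv_q(res$decisions, file.path(out_dir, "decisions.tsv"))
  logline("resolve_circular:", nrow(resolved), "resolved,",
          nrow(res$linear), "linear")

  assembly <- dplyr::bind_rows(
    res$linear,
    if (nrow(resolved) > 0)
      resolved %>% dplyr::select("id", "seq", "length", "depth", "circular"))
  write_fasta(assembly, file.path(out_dir, "final_assembly.fasta"))

  annotation <- NULL
  if (!is.null(library)) {
    annotation <- stage("annotate", annotate_assembly(
      assembly, library, cfg$min_identity, cfg$min_qcov))
    write_bed(annotation$hits, file.path(out_dir, "hits.bed"))
    write_gff3(annotation$hits, file.path(out_dir, "hits.gff3"))
    if (!is.null(annotation$status))
      write_tsv_q(annotation$status, file.path(out_dir, "status.tsv"))
    write_tsv_q(annotation$contig_map, file.path(out_dir, "contig_map.tsv"))
    logline("annotate:", nrow(annotation$hits), "hits,",
            if (is.null(annotation$status)) 0 else nrow(annotation$status),
            "constructs")
  }

  cn <- NULL
  depth_reads <- long_reads %||% short_reads
  if (!is.null(depth_reads) && !isFALSE(cfg$copy_number)) {
    cn <- stage("copy_number", {
      dp <- build_depth(assembly, reads = depth_reads)
      means <- vapply(dp$profiles, mean, numeric(1))
      base <- stats::median(rep(means, times = assembly$length %/% 1000L + 1L))
      tibble::tibble(contig = assembly$id, length = assembly$length,
                     mean_depth = means,
                     norm_depth = means / base)
    })
    write_tsv_q(cn, file.path(out_dir, "copy_number.tsv"))
    logline("copy_number:", nrow(cn), "contigs profiled")
  }

  t2t <- NULL
  if (!is.null(reference)) {
    t2t <- stage("t2t_completeness", t2t_completeness(
      assembly, reference, features %||% tibble::tibble(
        id = character(), seq = character(), category = character()),
      min_frac = cfg$t2t_min_frac))
    write_tsv_q(t2t$chromosomes, file.path(out_dir, "t2t.tsv"))
    logline("t2t:", sprintf("%.1f%% complete", t2t$percent_complete))
  }

  summary <- list(
    n_input_contigs = nrow(contigs),
    n_resolved_circular = nrow(resolved),
    n_linear = nrow(res$linear),
    n_final_contigs = nrow(assembly),
    verdicts = if (!is.null(annotation) && !is.null(annotation$status))
      as.list(table(annotation$status$verdict)) else NULL,
    percent_t2t_complete = if (!is.null(t2t)) t2t$percent_complete else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logline("done")
  invisible(list(assembly = assembly, resolution = res,
                 annotation = annotation, copy_number = cn, t2t = t2t,
                 out_dir = out_dir))
}
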