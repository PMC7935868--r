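#' Read a FASTA file into a contig table
#'
#' Sequences are uppercased and validated: A/C/G/T/N pass through, other
#' IUPAC ambiguity letters are mapped to N, and anything else (including U)
#' is an error.  All coordinates downstream of this reader are 0-based
#' half-open; conversion to 1-based happens only when writing GFF3.
#'
#' @param path FASTA file (plain or gzip).
#' @return A tibble with columns `id`, `seq`, `length`, `depth` (NA),
#'   `circular` (NA).  One row per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- unname(toupper(as.character(recs)))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad))
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  seqs <- chartr("RYSWKMBDHV", strrep("N", 10), seqs)
  as_contigs(ids, seqs)
}

as_contigs <- function(id, seq, depth = NA_real_, circular = NA) {
  tibble::tibble(id = id, seq = seq, length = nchar(seq),
                 depth = as.numeric(depth), circular = as.logical(circular))
}

#' Write contigs to FASTA
#'
#' @param contigs Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- contigs$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (plain or gzip).
#' @param platform Read platform tag: one of `"long"`, `"short_r1"`,
#'   `"short_r2"`.
#' @return A tibble with columns `id`, `seq`, `qual`, `platform`.
#' @export
read_fastq <- function(path, platform = c("long", "short_r1", "short_r2")) {
  platform <- match.arg(platform)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  while (length(lines) > 0 && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record at record index ", length(lines) %/% 4 + 1)
  n <- length(lines) %/% 4
  heads <- lines[seq(1, length(lines), by = 4)]
  seqs  <- toupper(lines[seq(2, length(lines), by = 4)])
  quals <- lines[seq(4, length(lines), by = 4)]
  if (!all(startsWith(heads, "@")))
    stop("malformed FASTQ header at record index ",
         which(!startsWith(heads, "@"))[1])
  bad <- nchar(quals) != nchar(seqs)
  if (any(bad))
    stop("quality length differs from sequence length at record index ",
         which(bad)[1])
  tibble::tibble(id = sub("\\s.*$", "", sub("^@", "", heads)),
                 seq = seqs, qual = quals, platform = platform)
}

#' Write reads to FASTQ
#'
#' Reads lacking qualities are written with constant Q40.
#'
#' @param reads Tibble with `id`, `seq` and optionally `qual`.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$seq)), qual)
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read assembler contig metadata
#'
#' Parses the info table emitted by long-read assemblers (name, length,
#' coverage/depth, circular flag).  Header matching is dialect-tolerant:
#' case-insensitive substring match on "circ", "len", "cov"/"depth", and the
#' first column (or one matching "name"/"contig"/"seq") is the contig id.
#' Circular values Y/N, +/-, True/False, 1/0 are all accepted.
#'
#' @param path Tab-separated file with a header row.
#' @return A tibble with columns `id`, `length`, `depth`, `circular`.
#' @export
read_assembly_metadata <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  h <- tolower(names(tab))
  pick <- function(pattern) {
    i <- grep(pattern, h)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  ic <- pick("name|contig|^seq|^#?id$")
  if (is.na(ic)) ic <- 1L
  il <- pick("len")
  iv <- pick("cov|depth")
  ir <- pick("circ")
  missing <- c(length = il, coverage = iv, circular = ir)
  if (anyNA(missing))
    stop("metadata lacks required column(s) ",
         paste(names(missing)[is.na(missing)], collapse = ", "),
         "; found columns: ", paste(names(tab), collapse = ", "))
  circ_raw <- toupper(trimws(as.character(tab[[ir]])))
  circ <- circ_raw %in% c("Y", "YES", "+", "TRUE", "T", "1")
  bad <- !circ & !circ_raw %in% c("N", "NO", "-", "FALSE", "F", "0")
  if (any(bad))
    stop("unrecognized circular flag value(s): ",
         paste(unique(circ_raw[bad]), collapse = ", "))
  len <- as.integer(tab[[il]])
  if (any(is.na(len)) || any(len < 1)) stop("metadata lengths must be >= 1")
  tibble::tibble(id = as.character(tab[[ic]]), length = len,
                 depth = as.numeric(tab[[iv]]), circular = circ)
}

#' Write assembler-style contig metadata
#'
#' @param metadata Tibble with `id`, `length`, `depth`, `circular`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assembly_metadata <- function(metadata, path) {
  out <- tibble::tibble(seq_name = metadata$id, length = metadata$length,
                        cov. = metadata$depth,
                        circ. = ifelse(metadata$circular, "Y", "N"))
  readr::write_tsv(out, path)
  invisible(path)
}

check_hits <- function(hits) {
  stopifnot(all(c("signature", "contig", "start", "end", "strand") %in% names(hits)))
  if (any(hits$end <= hits$start))
    stop("hit end must be greater than start (0-based half-open)")
  invisible(hits)
}

#' Write signature hits as BED6
#'
#' BED is 0-based half-open; the score column carries identity scaled to
#' 0-1000.
#'
#' @param hits Hit tibble (`signature`, `contig`, `start`, `end`, `strand`,
#'   optionally `identity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  check_hits(hits)
  score <- if ("identity" %in% names(hits)) round(hits$identity * 10) else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$contig, hits$start,
                   hits$end, hits$signature, as.integer(score), hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write signature hits as GFF3
#'
#' GFF3 is 1-based inclusive: a 0-based half-open hit `[start, end)` becomes
#' `start+1 .. end`.  The feature type column carries the signature
#' category; attributes carry the signature id.
#'
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hits, path) {
  check_hits(hits)
  type <- if ("category" %in% names(hits)) hits$category else "region"
  score <- if ("identity" %in% names(hits)) sprintf("%.1f", hits$identity) else "."
  lines <- c("##gff-version 3",
             if (nrow(hits) > 0)
               sprintf("%s\tcircsig\t%s\t%d\t%d\t%s\t%s\t.\tID=%s;signature=%s",
                       hits$contig, type, hits$start + 1L, hits$end, score,
                       hits$strand,
                       paste0(hits$signature, "_", seq_len(nrow(hits))),
                       hits$signature))
  writeLines(lines, path)
  invisible(path)
}
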