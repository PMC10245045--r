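#' Read long reads from FASTA or FASTQ
#'
#' Parses a (possibly gzip-compressed) FASTA or 4-line FASTQ file into the
#' package's canonical read table. Record order is preserved, duplicate read
#' ids are rejected, and any base outside `A/C/G/T` (including IUPAC `N`) is
#' replaced by `A` -- the pipeline reserves `N` as its mask character, so raw
#' sequences must never contain it. The number of replaced bases is reported.
#'
#' @param path input file; `.gz` handled transparently.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (sniffed from the
#'   extension, defaulting to FASTA).
#' @return a tibble with columns `read_id`, `sequence` and `quality`
#'   (character, `NA` for FASTA input).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGTA"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(set))
    reads <- tibble::tibble(read_id = ids,
                            sequence = unname(as.character(set)),
                            quality = NA_character_)
  } else {
    reads <- parse_fastq(path)
  }
  dup <- reads$read_id[duplicated(reads$read_id)]
  if (length(dup) > 0)
    stop("duplicate read id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(reads$sequence)))
    stop("record ", which(!nzchar(reads$sequence))[1], ": empty sequence")
  reads$sequence <- clean_sequences(reads$sequence)
  reads
}

# 4-line FASTQ parser; errors name the offending record index.
parse_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0)
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  if (length(lines) %% 4 != 0)
    stop("FASTQ record ", length(lines) %/% 4 + 1, ": truncated record")
  n <- length(lines) %/% 4
  hd <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  qu <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad) > 0)
    stop("FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(pl, "+"))
  if (length(bad) > 0)
    stop("FASTQ record ", bad[1], ": separator line does not start with '+'")
  bad <- which(nchar(qu) != nchar(sq))
  if (length(bad) > 0)
    stop("FASTQ record ", bad[1], ": quality length (", nchar(qu[bad[1]]),
         ") differs from sequence length (", nchar(sq[bad[1]]), ")")
  tibble::tibble(read_id = sub("\\s.*$", "", sub("^@", "", hd)),
                 sequence = sq, quality = qu)
}

clean_sequences <- function(x) {
  x <- toupper(x)
  n_bad <- sum(vapply(gregexpr("[^ACGT]", x), function(m) sum(m > 0), numeric(1)))
  if (n_bad > 0) {
    x <- gsub("[^ACGT]", "A", x)
    rlang::inform(sprintf("replaced %d non-ACGT base(s) with 'A'", n_bad))
  }
  x
}

#' Write reads to FASTA or FASTQ
#'
#' Round-trips with [read_sequences()]: ids and sequences are reproduced
#' exactly. FASTA output is wrapped at 80 columns; FASTQ records missing
#' quality strings get a constant placeholder (`I`).
#'
#' @param reads tibble with `read_id` and `sequence` (optionally `quality`).
#' @param path output file; a `.gz` suffix enables compression.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(reads$sequence)
    names(set) <- reads$read_id
    Biostrings::writeXStringSet(set, path, width = 80L,
                                compress = grepl("\\.gz$", path))
  } else {
    qual <- if ("quality" %in% names(reads)) reads$quality else NA_character_
    qual <- ifelse(is.na(qual), strrep("I", nchar(reads$sequence)), qual)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    if (nrow(reads) > 0)
      writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Write / read simulator truth tables
#'
#' Tab-separated ground truth, one row per simulated read: originating gene
#' and isoform, strand, the covered transcript interval (0-based, half-open)
#' and the realised number of injected errors by type. Header lines starting
#' with `#` record provenance and are ignored on input.
#'
#' @param truth truth tibble as produced by [simulate_reads()].
#' @param path file path.
#' @param header optional character vector of `#`-prefixed comment lines.
#' @return `path` invisibly (write); truth tibble (read).
#' @export
write_truth <- function(truth, path, header = NULL) {
  cols <- c("read_id", "gene_id", "isoform_id", "strand",
            "transcript_start", "transcript_end",
            "n_mismatch", "n_insert", "n_delete")
  cols <- intersect(cols, names(truth))
  con <- file(path, "wt")
  if (!is.null(header)) writeLines(header, con)
  close(con)
  readr::write_tsv(truth[cols], path, append = !is.null(header),
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
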