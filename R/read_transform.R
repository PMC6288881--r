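# Read parsing and in-silico bisulfite conversion of reads (the keyed
# readRDD -> transRDD step: each record keeps its read id as the key).

#' Read sequencing reads from FASTQ or FASTA
#'
#' Format is auto-detected from the first non-empty character (`@` FASTQ,
#' `>` FASTA). Read ids are taken up to the first whitespace and must be
#' unique. Gzip-compressed input is accepted. Qualities are Phred+33.
#'
#' @param path Input file.
#' @return data.frame with columns `read_id`, `seq`, `qual` (`NA` for FASTA),
#'   in file order.
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop(sprintf("reads file not found: %s", path))
  con <- file(path, "r")  # transparently decompresses gzip
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop(sprintf("empty reads file: %s", path))
  first <- substr(lines[nonempty[1]], 1L, 1L)
  recs <- if (first == "@") .parse_fastq(lines, path)
          else if (first == ">") .parse_fasta(lines, path)
          else stop(sprintf("cannot detect FASTQ/FASTA format of %s", path))
  dup <- anyDuplicated(recs$read_id)
  if (dup)
    stop(sprintf("duplicate read id '%s' in %s", recs$read_id[dup], path))
  recs
}

.parse_fastq <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at end of %s (%d lines)", path, n))
  heads <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(substr(heads, 1L, 1L) != "@")
  if (length(bad))
    stop(sprintf("malformed FASTQ header at line %d of %s",
                 (bad[1] - 1L) * 4L + 1L, path))
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf("malformed FASTQ separator at line %d of %s",
                 (bad[1] - 1L) * 4L + 3L, path))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf(
      "FASTQ quality length does not match sequence length at line %d of %s",
      (bad[1] - 1L) * 4L + 4L, path))
  ids <- sub("\\s.*$", "", substring(heads, 2L))
  data.frame(read_id = ids, seq = toupper(seqs), qual = quals,
             stringsAsFactors = FALSE)
}

.parse_fasta <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  is_head <- startsWith(lines, ">")
  if (!is_head[1])
    stop(sprintf("FASTA must start with '>' in %s", path))
  grp <- cumsum(is_head)
  ids <- sub("\\s.*$", "", substring(lines[is_head], 2L))
  seqs <- vapply(split(lines[!is_head], grp[!is_head]), paste,
                 character(1), collapse = "")
  if (length(seqs) != length(ids) || any(nchar(seqs) == 0L))
    stop(sprintf("FASTA record with empty sequence in %s", path))
  data.frame(read_id = ids, seq = toupper(unname(seqs)), qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Mean-quality read filter
#'
#' Keeps a read iff its mean Phred+33 quality is at least `min_mean_q`.
#' Records without qualities (FASTA) are always kept, and `min_mean_q = 0`
#' disables the filter entirely.
#'
#' @param qual Quality string (or `NA`).
#' @param min_mean_q Minimum mean Phred score; default 0 (off).
#' @return `TRUE` to keep, `FALSE` to drop. Vectorized over `qual`.
#' @export
quality_filter <- function(qual, min_mean_q = 0) {
  if (min_mean_q <= 0) return(rep(TRUE, length(qual)))
  vapply(qual, function(q) {
    if (is.na(q)) return(TRUE)
    codes <- utf8ToInt(q)
    if (any(codes < 33L | codes > 126L))
      stop("non-printable character in quality string")
    mean(codes - 33L) >= min_mean_q
  }, logical(1), USE.NAMES = FALSE)
}

#' In-silico three-letter conversion of a read
#'
#' Produces the CT- and GA-converted forms of a read; the original sequence is
#' carried alongside (it is needed for methylation calling downstream).
#'
#' @param read_id Read identifier.
#' @param seq Original read sequence.
#' @return List of two `TransformedRead` lists (`CT`, `GA`), each with
#'   `read_id`, `conv`, `conv_seq`, `orig_seq`.
#' @export
transform_read <- function(read_id, seq) {
  list(
    CT = list(read_id = read_id, conv = "CT",
              conv_seq = convert_sequence(seq, "CT"), orig_seq = seq),
    GA = list(read_id = read_id, conv = "GA",
              conv_seq = convert_sequence(seq, "GA"), orig_seq = seq)
  )
}
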