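# Seed-and-extend mapping of converted reads against converted genomes,
# producing per-conversion-pair candidate hits.

#' Candidate (read conversion, genome tag) pairs for a library mode
#'
#' Non-directional libraries sequence all four bisulfite strands, so both read
#' conversions are mapped (CT reads to the CT genomes, GA reads to the GA
#' genomes). Directional libraries contain only the original top/bottom
#' strands, so only the CT conversion is mapped.
#'
#' @param library `"non-directional"` or `"directional"`.
#' @return data.frame with columns `conv` and `genome_tag`.
#' @export
candidate_pairs <- function(library = c("non-directional", "directional")) {
  library <- match.arg(library)
  if (library == "non-directional") {
    data.frame(conv = c("CT", "CT", "GA", "GA"),
               genome_tag = c("W-CT", "C-CT", "W-GA", "C-GA"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(conv = c("CT", "CT"), genome_tag = c("W-CT", "C-CT"),
               stringsAsFactors = FALSE)
  }
}

#' Align one transformed read against a converted genome
#'
#' End-to-end ungapped placement search: exact k-mer seeds are taken at read
#' offsets 0, k, 2k, ... and every candidate placement is verified by
#' full-length Hamming comparison in converted space. Every placement with at
#' most `floor(read_len / k) - 1` mismatches is guaranteed to be found
#' (pigeonhole); 0-mismatch recall is total.
#'
#' @param tr A `TransformedRead` list (see [transform_read()]).
#' @param genome The `ConvertedGenome` being searched (must be conversion
#'   compatible: CT reads against `*-CT` genomes, GA reads against `*-GA`).
#' @param index `seed_index` built over `genome`.
#' @param max_mm Maximum mismatch count (inclusive).
#' @return data.frame of hits: `read_id`, `pair_tag`, `seq_name`, `pos`
#'   (0-based on the converted genome's own orientation), `mismatches`,
#'   `read_len`. Reads shorter than the seed length yield no hits, with a
#'   warning.
#' @export
align_read <- function(tr, genome, index, max_mm = 4L) {
  stopifnot(inherits(genome, "ConvertedGenome"), inherits(index, "seed_index"))
  if (!endsWith(genome$tag, tr$conv))
    stop(sprintf("conversion %s is not compatible with genome %s",
                 tr$conv, genome$tag))
  align_batch(tr$read_id, tr$conv_seq, index, genome$tag, max_mm)
}

#' Align a batch of converted reads against one converted genome
#'
#' Vectorized form of [align_read()]; used by the pipeline.
#'
#' @param read_ids,conv_seqs Parallel vectors of read ids and converted
#'   sequences.
#' @param index `seed_index` over the target converted genome.
#' @param pair_tag The genome tag recorded on each hit.
#' @param max_mm Maximum mismatch count.
#' @return Hits data.frame as in [align_read()].
#' @export
align_batch <- function(read_ids, conv_seqs, index, pair_tag, max_mm = 4L) {
  stopifnot(length(read_ids) == length(conv_seqs))
  short <- nchar(conv_seqs) < index$k
  if (any(short))
    warning(sprintf("%d read(s) shorter than seed length %d skipped (unmapped)",
                    sum(short), index$k))
  hits <- cpp_align_batch(conv_seqs, index$ptr, as.integer(max_mm))
  data.frame(
    read_id = read_ids[hits$read],
    pair_tag = rep(pair_tag, nrow(hits)),
    seq_name = index$seq_names[hits$seq],
    pos = hits$pos,
    mismatches = hits$mismatches,
    read_len = nchar(conv_seqs)[hits$read],
    stringsAsFactors = FALSE
  )
}

#' Align through an external three-letter backend
#'
#' Adapter for delegating the mapping step to an external aligner (e.g. a
#' Bowtie2 wrapper). The backend is invoked once per converted-genome target
#' with a FASTA of converted reads and must produce SAM with an `NM` tag; the
#' SAM is parsed back into the same hit semantics as [align_read()], dropping
#' hits whose edit distance exceeds `max_mm`.
#'
#' @param read_ids,conv_seqs Converted read batch.
#' @param genome_fasta Path to the converted genome FASTA to align against.
#' @param pair_tag Tag recorded on the parsed hits.
#' @param backend List with `cmd` (executable) and `args` (character vector;
#'   occurrences of `{reads}`, `{genome}`, `{out}` are substituted).
#' @param max_mm Maximum mismatch count.
#' @return Hits data.frame as in [align_read()].
#' @export
external_backend_align <- function(read_ids, conv_seqs, genome_fasta, pair_tag,
                                   backend, max_mm = 4L) {
  if (is.null(backend$cmd) || !nzchar(Sys.which(backend$cmd)))
    stop(sprintf(
      "alignment backend '%s' not found on PATH; use the internal aligner (backend = \"internal\")",
      if (is.null(backend$cmd)) "<unset>" else backend$cmd))
  reads_fa <- tempfile(fileext = ".fa")
  out_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(c(reads_fa, out_sam)))
  writeLines(paste0(">", read_ids, "\n", conv_seqs), reads_fa)
  args <- backend$args
  args <- gsub("{reads}", reads_fa, args, fixed = TRUE)
  args <- gsub("{genome}", genome_fasta, args, fixed = TRUE)
  args <- gsub("{out}", out_sam, args, fixed = TRUE)
  status <- system2(backend$cmd, args, stdout = FALSE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0L)
    stop(sprintf("backend '%s' failed (exit %d): %s", backend$cmd,
                 attr(status, "status"), paste(status, collapse = "; ")))
  parse_backend_sam(out_sam, pair_tag, max_mm)
}

#' Parse backend SAM output into alignment hits
#'
#' Accepts minimal SAM: mapped primary records with an `NM:i:` tag. Positions
#' are converted to 0-based; records with edit distance above `max_mm` are
#' excluded.
#'
#' @param path SAM file.
#' @param pair_tag Tag recorded on each hit.
#' @param max_mm Maximum mismatch count.
#' @return Hits data.frame as in [align_read()].
#' @export
parse_backend_sam <- function(path, pair_tag, max_mm = 4L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- list(read_id = character(0), pair_tag = character(0),
              seq_name = character(0), pos = integer(0),
              mismatches = integer(0), read_len = integer(0))
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop(sprintf("malformed SAM record: %s", ln))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L) next  # unmapped/secondary
    nm_field <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (!length(nm_field))
      stop(sprintf("backend SAM record lacks NM tag: %s", f[1]))
    nm <- as.integer(sub("^NM:i:", "", nm_field[1]))
    if (nm > max_mm) next
    out$read_id <- c(out$read_id, f[1])
    out$pair_tag <- c(out$pair_tag, pair_tag)
    out$seq_name <- c(out$seq_name, f[3])
    out$pos <- c(out$pos, as.integer(f[4]) - 1L)
    out$mismatches <- c(out$mismatches, nm)
    out$read_len <- c(out$read_len, nchar(f[10]))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
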