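# Best-alignment resolution: merge the four per-pair hit streams, keep the
# uniquely-least-mismatch placement per read, discard ambiguous reads, and
# lift Crick coordinates onto the Watson strand.

#' Lift a Crick-orientation coordinate onto the Watson strand
#'
#' Crick genomes are stored reverse-complemented, so a hit at 0-based `pos_c`
#' covers Watson positions `[seq_len - pos_c - read_len, seq_len - pos_c)`.
#'
#' @param pos_c 0-based start on the Crick-oriented sequence.
#' @param read_len Read length.
#' @param seq_len Watson sequence length.
#' @return 0-based Watson start position. Vectorized.
#' @export
crick_to_watson <- function(pos_c, read_len, seq_len) {
  if (any(pos_c < 0L | pos_c > seq_len - read_len))
    stop("crick_to_watson: position out of range")
  seq_len - pos_c - read_len
}

.watson_strand <- function(pair_tag) {
  ifelse(pair_tag %in% c("W-CT", "W-GA"), "+", "-")
}

# Add watson_pos / watson_strand columns to a hits data.frame.
.lift_hits <- function(hits, source_lengths) {
  if (!nrow(hits)) {
    hits$watson_pos <- integer(0)
    hits$watson_strand <- character(0)
    return(hits)
  }
  seq_len <- unname(source_lengths[hits$seq_name])
  crick <- hits$pair_tag %in% c("C-CT", "C-GA")
  wp <- hits$pos
  wp[crick] <- crick_to_watson(hits$pos[crick], hits$read_len[crick],
                               seq_len[crick])
  hits$watson_pos <- wp
  hits$watson_strand <- .watson_strand(hits$pair_tag)
  hits
}

#' Select the unique best alignment for one read
#'
#' Coincident placements reported through more than one conversion pair
#' (identical sequence, Watson position and strand — e.g. a read without
#' unconverted cytosines hits both the CT and GA genome of a strand) are
#' deduplicated first, keeping the hit with the fewest mismatches (ties broken
#' by tag order W-CT, W-GA, C-CT, C-GA). Then the placement with the uniquely smallest mismatch count wins; a
#' tie at the minimum makes the read ambiguous and it is discarded; no hits
#' means unmapped. The mismatch cutoff is re-checked here.
#'
#' @param hits data.frame of `AlignmentHit` rows for a single read (columns
#'   `read_id`, `pair_tag`, `seq_name`, `pos`, `mismatches`, `read_len`).
#' @param source_lengths Named integer vector of Watson sequence lengths.
#' @param max_mm Mismatch cutoff (re-applied).
#' @return List with `status` (`"resolved"`, `"ambiguous"` or `"unmapped"`)
#'   and, when resolved, `alignment`: a one-row data.frame with `read_id`,
#'   `pair_tag`, `seq_name`, `watson_pos`, `watson_strand`, `mismatches`,
#'   `read_len`.
#' @export
select_best <- function(hits, source_lengths, max_mm = 4L) {
  if (nrow(hits) == 0L) return(list(status = "unmapped", alignment = NULL))
  if (length(unique(hits$read_id)) != 1L)
    stop("select_best expects hits for exactly one read")
  if (length(unique(hits$read_len)) != 1L)
    stop("inconsistent read_len across hits for one read")
  hits <- hits[hits$mismatches <= max_mm, , drop = FALSE]
  if (nrow(hits) == 0L) return(list(status = "unmapped", alignment = NULL))
  hits <- .lift_hits(hits, source_lengths)
  hits <- hits[order(hits$mismatches, match(hits$pair_tag, CONVERSION_TAGS)), ,
               drop = FALSE]
  dup <- duplicated(hits[, c("seq_name", "watson_pos", "watson_strand")])
  hits <- hits[!dup, , drop = FALSE]
  best <- min(hits$mismatches)
  at_best <- which(hits$mismatches == best)
  if (length(at_best) > 1L) return(list(status = "ambiguous", alignment = NULL))
  aln <- hits[at_best, c("read_id", "pair_tag", "seq_name", "watson_pos",
                         "watson_strand", "mismatches", "read_len")]
  rownames(aln) <- NULL
  list(status = "resolved", alignment = aln)
}

#' Resolve a full hit table
#'
#' Vectorized application of the [select_best()] rule over all reads in a hits
#' table. Output is independent of row order.
#'
#' @param hits Combined hits data.frame (all conversion pairs).
#' @param source_lengths Named integer vector of Watson sequence lengths.
#' @param max_mm Mismatch cutoff.
#' @return List with `resolved` (data.frame of resolved alignments, one row
#'   per read, ordered by read_id) and `ambiguous_ids` (character).
#' @export
resolve_hits <- function(hits, source_lengths, max_mm = 4L) {
  empty <- data.frame(read_id = character(0), pair_tag = character(0),
                      seq_name = character(0), watson_pos = integer(0),
                      watson_strand = character(0), mismatches = integer(0),
                      read_len = integer(0), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(resolved = empty, ambiguous_ids = character(0)))
  hits <- hits[hits$mismatches <= max_mm, , drop = FALSE]
  if (!nrow(hits)) return(list(resolved = empty, ambiguous_ids = character(0)))
  dt <- data.table::as.data.table(.lift_hits(hits, source_lengths))
  dt[, tag_rank := match(pair_tag, CONVERSION_TAGS)]
  data.table::setorder(dt, read_id, mismatches, tag_rank)
  dt <- unique(dt, by = c("read_id", "seq_name", "watson_pos", "watson_strand"))
  dt[, best := min(mismatches), by = read_id]
  dt <- dt[mismatches == best]
  dt[, n_best := .N, by = read_id]
  ambiguous_ids <- unique(dt[n_best > 1L]$read_id)
  res <- dt[n_best == 1L,
            .(read_id, pair_tag, seq_name, watson_pos, watson_strand,
              mismatches, read_len)]
  data.table::setorder(res, read_id)
  list(resolved = as.data.frame(res), ambiguous_ids = ambiguous_ids)
}

#' Merge co-partitioned hit streams partition-locally
#'
#' The four per-pair hit streams are keyed by read id and partitioned with the
#' same partitioner, so every hit of a read already lives in the same
#' partition index; merging is then a per-partition concatenation and moves no
#' records across partitions (the zero-shuffle contract). The partitioner of
#' the inputs is preserved and the movement counter is unchanged.
#'
#' @param streams List of `partitioned_stream`s sharing partitioner and
#'   partition count.
#' @return A merged `partitioned_stream`.
#' @export
merge_copartitioned <- function(streams) {
  merged <- co_union(streams)
  # contract assertion: all hits of any read share one partition index
  key_part <- data.table::rbindlist(lapply(seq_along(merged$partitions),
    function(i) {
      p <- merged$partitions[[i]]
      if (is.null(p) || nrow(p) == 0L) return(NULL)
      data.table::data.table(k = p$key, part = i)
    }))
  if (!is.null(key_part) && nrow(key_part)) {
    spread <- key_part[, data.table::uniqueN(part), by = "k"]$V1
    if (any(spread > 1L))
      stop("co-partitioning contract violated: a key spans multiple partitions")
  }
  merged
}
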