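# End-to-end pipeline over the partitioned engine.
#
# Phase 1  load reads into a keyed stream (chunked in input order, like
#          block-based input loading; optional hash repartition = first
#          rebalance point).
# Phase 2  quality filter, in-silico CT/GA conversion, seed-and-extend
#          alignment of each conversion pair -> four co-partitioned hit
#          streams keyed by read id.
# Phase 3  zero-shuffle co-partitioned merge, unique-best resolution,
#          ambiguity filtering (optional hash repartition of the survivors =
#          second rebalance point).
# Phase 4  methylation calling against the broadcast original reference
#          (staged once per partition), SAM + site report.

#' Run the full three-letter alignment pipeline
#'
#' @param genome_pack A `genome_pack` (see [prepare_genome()]) or the path of
#'   a saved pack directory.
#' @param reads Reads data.frame from [read_fastx()] or a FASTQ/FASTA path.
#' @param library Library protocol: `"non-directional"` maps both read
#'   conversions against all four genomes, `"directional"` maps only the CT
#'   conversion.
#' @param max_mm Mismatch cutoff (converted space).
#' @param min_mean_q Mean-quality filter threshold (0 disables).
#' @param n_partitions Number of partitions (default `workers * 4`).
#' @param workers Worker processes for partition-level work.
#' @param balance Enable rebalancing repartitions at the two imbalance points.
#' @param out_sam Optional SAM output path.
#' @param out_sites Optional per-site report TSV path.
#' @param out_stats Optional run-statistics JSON path.
#' @return List with `resolved` (alignments + calls), `site_counts`,
#'   `ambiguous_ids` (reads discarded by the uniqueness rule), and `stats`
#'   (counts, per-partition sizes, movement and staging counters).
#' @export
run_pipeline <- function(genome_pack, reads,
                         library = c("non-directional", "directional"),
                         max_mm = 4L, min_mean_q = 0, n_partitions = NULL,
                         workers = 1L, balance = FALSE, out_sam = NULL,
                         out_sites = NULL, out_stats = NULL) {
  library <- match.arg(library)
  if (is.character(genome_pack)) genome_pack <- load_genome_pack(genome_pack)
  stopifnot(inherits(genome_pack, "genome_pack"))
  if (is.character(reads)) reads <- read_fastx(reads)
  if (is.null(n_partitions)) n_partitions <- as.integer(workers) * 4L
  n_partitions <- max(1L, as.integer(n_partitions))

  stats <- list(library = library, max_mm = max_mm, min_mean_q = min_mean_q,
                n_partitions = n_partitions, workers = workers,
                balance = balance, reads_in = nrow(reads))

  # ---- Phase 1: keyed input stream --------------------------------------
  reads$key <- reads$read_id
  stream <- make_stream(reads, n_partitions, by = "chunk")
  stats$partition_sizes_input <- partition_sizes(stream)
  if (balance) stream <- make_stream(collect_stream(stream), n_partitions,
                                     by = "hash")
  stats$partition_sizes_phase1 <- partition_sizes(stream)

  # ---- Phase 2: transform + align per partition -------------------------
  pairs <- candidate_pairs(library)
  k <- genome_pack$k
  part_results <- .map_partitions(stream, function(p) {
    if (nrow(p) == 0L) {
      return(list(hits = setNames(vector("list", nrow(pairs)),
                                  pairs$genome_tag),
                  reads = p, dropped = 0L, too_short = 0L))
    }
    keep <- quality_filter(p$qual, min_mean_q)
    dropped <- sum(!keep)
    p <- p[keep, , drop = FALSE]
    too_short <- sum(nchar(p$seq) < k)
    bad <- grepl("[^ACGTN]", p$seq)
    if (any(bad))
      stop(sprintf("read %s contains a character outside {A,C,G,T,N}",
                   p$read_id[which(bad)[1]]))
    hits <- list()
    for (j in seq_len(nrow(pairs))) {
      conv <- pairs$conv[j]
      tag <- pairs$genome_tag[j]
      conv_seqs <- if (conv == "CT") chartr("C", "T", p$seq)
                   else chartr("G", "A", p$seq)
      h <- suppressWarnings(
        align_batch(p$read_id, conv_seqs, genome_pack$indexes[[tag]], tag,
                    max_mm))
      h$key <- h$read_id
      hits[[tag]] <- h
    }
    list(hits = hits, reads = p, dropped = dropped, too_short = too_short)
  }, workers)
  stats$quality_dropped <- sum(vapply(part_results, `[[`, integer(1), "dropped"))
  stats$too_short <- sum(vapply(part_results, `[[`, integer(1), "too_short"))

  # four hit streams inherit the read stream's layout -> co-partitioned by
  # construction (a read's hits are produced in the read's own partition)
  pid <- .partitioner_id(n_partitions)
  hit_streams <- lapply(pairs$genome_tag, function(tag) {
    structure(list(
      partitions = lapply(part_results, function(r) {
        h <- r$hits[[tag]]
        if (is.null(h)) .empty_hits() else h
      }),
      n_partitions = n_partitions, partitioner_id = pid, movement = 0L),
      class = "partitioned_stream")
  })

  # ---- Phase 3: zero-shuffle merge + unique-best resolution -------------
  merged <- merge_copartitioned(hit_streams)
  stats$phase3_movement <- merged$movement  # zero-shuffle contract
  src_len <- genome_pack$ref$lengths
  res_parts <- lapply(seq_len(n_partitions), function(i) {
    res <- resolve_hits(merged$partitions[[i]], src_len, max_mm)
    rd <- part_results[[i]]$reads
    if (nrow(res$resolved)) {
      res$resolved$orig_seq <- rd$seq[match(res$resolved$read_id, rd$read_id)]
      res$resolved$key <- res$resolved$read_id
    }
    res
  })
  ambiguous_ids <- unique(unlist(lapply(res_parts, `[[`, "ambiguous_ids")))
  stats$ambiguous <- length(ambiguous_ids)
  stats$resolved <- sum(vapply(res_parts,
                               function(r) nrow(r$resolved), integer(1)))
  stats$unmapped <- stats$reads_in - stats$quality_dropped - stats$ambiguous -
    stats$resolved

  resolved_stream <- structure(list(
    partitions = lapply(res_parts, function(r) {
      if (nrow(r$resolved)) r$resolved else .empty_resolved()
    }),
    n_partitions = n_partitions, partitioner_id = pid, movement = 0L),
    class = "partitioned_stream")
  stats$partition_sizes_filtered <- partition_sizes(resolved_stream)
  if (balance) resolved_stream <- repartition(resolved_stream, n_partitions)
  stats$partition_sizes_phase3 <- partition_sizes(resolved_stream)
  stats$rebalance_movement <- resolved_stream$movement

  # ---- Phase 4: methylation profiling -----------------------------------
  ref <- genome_pack$ref
  call_parts <- .map_partitions(resolved_stream, function(p) {
    if (nrow(p) == 0L) return(list(calls = character(0), sites = NULL,
                                   staged = 0L))
    cache <- .context_cache(ref)  # broadcast reference staged once here
    calls <- character(nrow(p))
    sites <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      cr <- call_read(p[i, , drop = FALSE], ref, cache)
      calls[i] <- cr$calls
      sites[[i]] <- cr$sites
    }
    list(calls = setNames(calls, p$read_id),
         sites = as.data.frame(data.table::rbindlist(sites)), staged = 1L)
  }, workers)
  stats$ref_stagings <- sum(vapply(call_parts, `[[`, integer(1), "staged"))

  resolved <- collect_stream(resolved_stream)
  resolved$key <- NULL
  calls <- do.call(c, lapply(call_parts, `[[`, "calls"))
  all_sites <- as.data.frame(
    data.table::rbindlist(lapply(call_parts, `[[`, "sites")))
  site_counts <- aggregate_sites(all_sites)
  resolved$calls <- unname(calls[resolved$read_id])

  if (!is.null(out_sam)) write_sam(resolved, calls, ref, out_sam)
  if (!is.null(out_sites)) write_site_report(site_counts, out_sites)
  if (!is.null(out_stats))
    jsonlite::write_json(stats, out_stats, auto_unbox = TRUE, digits = NA)

  list(resolved = resolved, site_counts = site_counts,
       ambiguous_ids = as.character(ambiguous_ids), stats = stats)
}

.empty_hits <- function() {
  data.frame(read_id = character(0), pair_tag = character(0),
             seq_name = character(0), pos = integer(0),
             mismatches = integer(0), read_len = integer(0),
             key = character(0), stringsAsFactors = FALSE)
}

.empty_resolved <- function() {
  data.frame(read_id = character(0), pair_tag = character(0),
             seq_name = character(0), watson_pos = integer(0),
             watson_strand = character(0), mismatches = integer(0),
             read_len = integer(0), orig_seq = character(0),
             key = character(0), stringsAsFactors = FALSE)
}
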