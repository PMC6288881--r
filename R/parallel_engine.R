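# Keyed-partition data-flow executor: deterministic hash partitioning,
# co-partitioned union (zero shuffle), rebalancing repartition and movement
# accounting. A local stand-in for a distributed keyed-RDD engine that
# preserves its contracts.

#' Deterministic portable hash of record keys
#'
#' FNV-1a 64-bit over the key bytes. Stable across runs, platforms and
#' processes (no per-process randomization), which is what makes hash
#' partitioning reproducible.
#'
#' @param keys Character vector.
#' @return Lowercase 16-digit hex strings. `portable_hash("")` is the FNV-1a
#'   offset basis `cbf29ce484222325`.
#' @export
portable_hash <- function(keys) {
  cpp_fnv1a64_hex(as.character(keys))
}

#' Partition ids for keys
#'
#' @param keys Character vector.
#' @param n Number of partitions.
#' @return 1-based partition indexes `portable_hash(key) mod n + 1`.
#' @export
partition_of <- function(keys, n) {
  cpp_fnv1a64_mod(as.character(keys), as.integer(n))
}

.partitioner_id <- function(n) sprintf("fnv1a64:%d", as.integer(n))

#' Construct a partitioned stream
#'
#' A `partitioned_stream` holds keyed records (data.frames with a `key`
#' column) split across `n` partitions, plus the identity of the partitioner
#' that placed them (or `NA` when records were merely chunked, e.g. in input
#' file order) and a cumulative cross-partition movement counter.
#'
#' @param records data.frame with a `key` column.
#' @param n Number of partitions (>= 1).
#' @param by `"hash"` places each record by [partition_of()]; `"chunk"` splits
#'   the input into `n` contiguous chunks in order (no partitioner attached),
#'   mimicking block-based input loading, which is one of the two imbalance
#'   points the rebalancing mode addresses.
#' @return A `partitioned_stream`.
#' @export
make_stream <- function(records, n, by = c("hash", "chunk")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(records), "key" %in% names(records), n >= 1L)
  n <- as.integer(n)
  if (by == "hash") {
    idx <- partition_of(records$key, n)
    pid <- .partitioner_id(n)
  } else {
    nr <- nrow(records)
    idx <- if (nr) ceiling(seq_len(nr) * n / nr) else integer(0)
    pid <- NA_character_
  }
  parts <- lapply(seq_len(n), function(i) records[idx == i, , drop = FALSE])
  structure(list(partitions = parts, n_partitions = n, partitioner_id = pid,
                 movement = 0L),
            class = "partitioned_stream")
}

#' @export
print.partitioned_stream <- function(x, ...) {
  cat(sprintf(
    "partitioned_stream: %d partition(s) [%s], partitioner=%s, moved=%d\n",
    x$n_partitions, paste(partition_sizes(x), collapse = ","),
    ifelse(is.na(x$partitioner_id), "<none>", x$partitioner_id), x$movement))
  invisible(x)
}

#' Per-partition record counts
#' @param stream A `partitioned_stream`.
#' @return Integer vector of partition sizes.
#' @export
partition_sizes <- function(stream) {
  vapply(stream$partitions, nrow, integer(1))
}

#' Collect a stream back into a single data.frame
#' @param stream A `partitioned_stream`.
#' @return data.frame of all records (partition order).
#' @export
collect_stream <- function(stream) {
  as.data.frame(data.table::rbindlist(stream$partitions))
}

#' Repartition a stream by key hash
#'
#' Every record moves to partition `portable_hash(key) mod n`; the movement
#' counter is incremented once per record that changes partition. Applying the
#' same (hash, n) twice moves nothing the second time.
#'
#' @param stream A `partitioned_stream`.
#' @param n Target partition count.
#' @return Rebalanced `partitioned_stream`.
#' @export
repartition <- function(stream, n = stream$n_partitions) {
  stopifnot(inherits(stream, "partitioned_stream"), n >= 1L)
  n <- as.integer(n)
  moved <- 0L
  shards <- vector("list", 0L)
  for (i in seq_along(stream$partitions)) {
    p <- stream$partitions[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    tgt <- partition_of(p$key, n)
    moved <- moved + sum(tgt != i | i > n)
    p$.tgt <- tgt
    shards[[length(shards) + 1L]] <- p
  }
  all <- data.table::rbindlist(shards)
  parts <- lapply(seq_len(n), function(i) {
    if (is.null(all) || nrow(all) == 0L)
      return(stream$partitions[[1]][0, , drop = FALSE])
    out <- as.data.frame(all[all$.tgt == i, , drop = FALSE])
    out$.tgt <- NULL
    out
  })
  structure(list(partitions = parts, n_partitions = n,
                 partitioner_id = .partitioner_id(n),
                 movement = stream$movement + moved),
            class = "partitioned_stream")
}

#' Co-partitioned union
#'
#' Concatenates partition i of every input into partition i of the output.
#' Requires all inputs to share the same partitioner identity and partition
#' count; under that contract no record crosses a partition boundary, so the
#' movement counter of the result is the sum of the inputs' counters with no
#' additional movement (zero-shuffle).
#'
#' @param streams List of `partitioned_stream`s.
#' @return Unioned `partitioned_stream`.
#' @export
co_union <- function(streams) {
  stopifnot(length(streams) >= 1L)
  pid <- streams[[1]]$partitioner_id
  n <- streams[[1]]$n_partitions
  for (s in streams) {
    if (!inherits(s, "partitioned_stream"))
      stop("co_union expects partitioned_stream inputs")
    if (s$n_partitions != n)
      stop("co_union contract violation: partition counts differ")
    if (!identical(s$partitioner_id, pid) || is.na(pid))
      stop("co_union contract violation: streams do not share a partitioner")
  }
  parts <- lapply(seq_len(n), function(i) {
    as.data.frame(data.table::rbindlist(lapply(streams,
                                               function(s) s$partitions[[i]])))
  })
  structure(list(partitions = parts, n_partitions = n, partitioner_id = pid,
                 movement = sum(vapply(streams, function(s) s$movement,
                                       integer(1)))),
            class = "partitioned_stream")
}

# Apply FUN to each partition (optionally in parallel worker processes).
.map_partitions <- function(stream, FUN, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(stream$partitions, FUN, mc.cores = workers)
  } else {
    lapply(stream$partitions, FUN)
  }
}
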