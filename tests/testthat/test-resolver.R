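.hit <- function(read_id = "r1", pair_tag = "W-CT", seq_name = "s", pos = 0L,
                 mismatches = 0L, read_len = 4L) {
  data.frame(read_id = read_id, pair_tag = pair_tag, seq_name = seq_name,
             pos = pos, mismatches = mismatches, read_len = read_len,
             stringsAsFactors = FALSE)
}

test_that("select_best applies the uniquely-least-mismatch rule", {
  src <- c(s = 100L)
  h <- rbind(.hit(pos = 0L, mismatches = 0L),
             .hit(pos = 10L, mismatches = 2L),
             .hit(pos = 20L, mismatches = 3L))
  r <- select_best(h, src)
  expect_identical(r$status, "resolved")
  expect_identical(r$alignment$watson_pos, 0L)
  expect_identical(r$alignment$mismatches, 0L)

  h2 <- rbind(.hit(pos = 0L, mismatches = 1L),
              .hit(pos = 10L, mismatches = 1L),
              .hit(pos = 20L, mismatches = 3L))
  expect_identical(select_best(h2, src)$status, "ambiguous")

  expect_identical(select_best(.hit()[0, ], src)$status, "unmapped")

  # the cutoff is re-checked
  h3 <- .hit(mismatches = 5L)
  expect_identical(select_best(h3, src, max_mm = 4L)$status, "unmapped")

  # inconsistent read_len is an internal error
  h4 <- rbind(.hit(read_len = 4L), .hit(pos = 5L, read_len = 6L))
  expect_error(select_best(h4, src), "read_len")
})

test_that("coincident hits from two conversion pairs dedup to one placement", {
  # a read with every C methylated matches both W-CT and W-GA at the same
  # Watson locus; without dedup it would self-tie and be lost
  src <- c(s = 100L)
  h <- rbind(.hit(pair_tag = "W-CT", pos = 7L, mismatches = 0L),
             .hit(pair_tag = "W-GA", pos = 7L, mismatches = 0L))
  r <- select_best(h, src)
  expect_identical(r$status, "resolved")
  expect_identical(r$alignment$pair_tag, "W-CT")  # canonical tag order
  # distinct Watson loci still tie
  h2 <- rbind(.hit(pair_tag = "W-CT", pos = 7L, mismatches = 0L),
              .hit(pair_tag = "W-GA", pos = 9L, mismatches = 0L))
  expect_identical(select_best(h2, src)$status, "ambiguous")
})

test_that("crick_to_watson lifts coordinates and is an involution", {
  expect_identical(crick_to_watson(0L, 4L, 10L), 6L)
  expect_identical(crick_to_watson(6L, 4L, 10L), 0L)
  set.seed(107)
  for (i in 1:20) {
    slen <- sample(50:500, 1)
    rl <- sample(10:40, 1)
    pc <- sample(0:(slen - rl), 1)
    expect_identical(crick_to_watson(crick_to_watson(pc, rl, slen), rl, slen),
                     pc)
  }
  expect_error(crick_to_watson(8L, 4L, 10L), "out of range")
})

test_that("crick hits lift to the Watson strand with '-' orientation", {
  src <- c(s = 10L)
  h <- .hit(pair_tag = "C-CT", pos = 0L, read_len = 4L)
  r <- select_best(h, src)
  expect_identical(r$alignment$watson_pos, 6L)
  expect_identical(r$alignment$watson_strand, "-")
})

test_that("select_best is permutation invariant and matches resolve_hits", {
  set.seed(108)
  src <- c(s1 = 200L, s2 = 150L)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(j) {
      .hit(pair_tag = sample(c("W-CT", "W-GA", "C-CT", "C-GA"), 1),
           seq_name = sample(names(src), 1),
           pos = sample(0:100, 1), mismatches = sample(0:4, 1),
           read_len = 20L)
    }))
    base <- select_best(h, src)
    perm <- select_best(h[sample(nrow(h)), , drop = FALSE], src)
    expect_identical(base$status, perm$status)
    if (base$status == "resolved")
      expect_identical(base$alignment, perm$alignment)
    # vectorized resolver agrees
    v <- resolve_hits(h, src)
    if (base$status == "resolved") {
      expect_identical(nrow(v$resolved), 1L)
      expect_identical(v$resolved$watson_pos, base$alignment$watson_pos)
    } else if (base$status == "ambiguous") {
      expect_identical(v$ambiguous_ids, "r1")
    } else {
      expect_identical(nrow(v$resolved), 0L)
      expect_length(v$ambiguous_ids, 0L)
    }
  }
})

test_that("pipeline resolution equals the naive all-offset four-genome oracle", {
  set.seed(109)
  ref <- synth_genome(3000, seed = 109, seq_name = "chr")
  pack <- prepare_genome(ref, k = 6)
  cfg <- sim_config(n_reads = 60, read_len = 36, error_rate = 0.02, seed = 12)
  sim <- simulate_reads(cfg, ref)
  res <- run_pipeline(pack, toy_reads_df(sim$reads$read_id, sim$reads$seq,
                                         sim$reads$qual))
  for (i in seq_len(nrow(sim$reads))) {
    o <- oracle_resolve(sim$reads$seq[i], ref$sequences, max_mm = 4L)
    got <- res$resolved[res$resolved$read_id == sim$reads$read_id[i], ]
    if (o$status == "resolved") {
      expect_identical(nrow(got), 1L)
      expect_identical(got$watson_pos, o$watson_pos)
      expect_identical(got$watson_strand, o$strand)
      expect_identical(got$mismatches, o$mm)
    } else {
      expect_identical(nrow(got), 0L)
      expect_identical(sim$reads$read_id[i] %in% res$ambiguous_ids,
                       o$status == "ambiguous")
    }
  }
  # count conservation
  expect_identical(res$stats$reads_in,
                   res$stats$resolved + res$stats$ambiguous +
                     res$stats$unmapped + res$stats$quality_dropped)
})

test_that("merge_copartitioned rejects mismatched streams", {
  df <- data.frame(key = c("a", "b"), x = 1:2, stringsAsFactors = FALSE)
  s2 <- make_stream(df, 2)
  s3 <- make_stream(df, 3)
  expect_error(merge_copartitioned(list(s2, s3)), "partition counts differ")
  chunked <- make_stream(df, 2, by = "chunk")
  expect_error(merge_copartitioned(list(s2, chunked)), "partitioner")
  # happy path: movement stays zero
  m <- merge_copartitioned(list(s2, s2))
  expect_identical(m$movement, 0L)
  expect_identical(nrow(collect_stream(m)), 4L)
})

test_that("single-partition merge equals naive global grouping", {
  set.seed(110)
  dfs <- lapply(1:4, function(i) {
    data.frame(key = sample(letters[1:6], 8, replace = TRUE), v = i,
               stringsAsFactors = FALSE)
  })
  streams <- lapply(dfs, make_stream, n = 1L)
  merged <- collect_stream(merge_copartitioned(streams))
  naive <- do.call(rbind, dfs)
  expect_identical(table(merged$key), table(naive$key))
  expect_identical(nrow(merged), nrow(naive))
})
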