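.raln <- function(read_id = "r1", pair_tag = "W-CT", seq_name = "s",
                  watson_pos = 0L, watson_strand = "+", mismatches = 0L,
                  orig_seq = "ACGA") {
  data.frame(read_id = read_id, pair_tag = pair_tag, seq_name = seq_name,
             watson_pos = watson_pos, watson_strand = watson_strand,
             mismatches = mismatches, read_len = nchar(orig_seq),
             orig_seq = orig_seq, stringsAsFactors = FALSE)
}

test_that("classify_context follows the strand-aware downstream rule", {
  ref <- reference_genome(c(s = "ACGTACAGACAA"))
  expect_identical(classify_context(ref, "s", 1L, "+"), "CpG")   # A[CG]T
  expect_identical(classify_context(ref, "s", 5L, "+"), "CHG")   # C-A-G
  expect_identical(classify_context(ref, "s", 9L, "+"), "CHH")   # C-A-A
  # minus strand: G on Watson, downstream = upstream complemented
  ref2 <- reference_genome(c(s = "ACGT"))
  expect_identical(classify_context(ref2, "s", 2L, "-"), "CpG")  # CG pair
  expect_error(classify_context(ref, "s", 0L, "+"), "not a cytosine")
  # incomplete context at the sequence end -> CHH, flagged
  ref3 <- reference_genome(c(s = "AAC"))
  ctx <- classify_context(ref3, "s", 2L, "+")
  expect_identical(as.character(ctx), "CHH")
  expect_true(isTRUE(attr(ctx, "incomplete")))
})

test_that("call_read covers the spec examples", {
  ref <- reference_genome(c(s = "ACGA"))
  expect_identical(call_read(.raln(orig_seq = "ACGA"), ref)$calls, ".Z..")
  expect_identical(call_read(.raln(orig_seq = "ATGA"), ref)$calls, ".z..")
  ref2 <- reference_genome(c(s = "ACAA"))
  expect_identical(call_read(.raln(orig_seq = "ACAA"), ref2)$calls, ".H..")
  # sequencing error over a reference C -> no information
  expect_identical(call_read(.raln(orig_seq = "AGGA"), ref)$calls, "....")
})

test_that("call_read handles all four conversion-pair geometries", {
  # Watson: pos 0123456; C at 2 (CpG with G at 3), G at 3
  ref <- reference_genome(c(s = "ATCGATT"))
  # W-CT '+': read C over ref C -> methylated CpG on '+'
  cr <- call_read(.raln(pair_tag = "W-CT", watson_pos = 0L, orig_seq = "ATCGATT"),
                  ref)
  expect_identical(cr$calls, "..Z....")
  expect_identical(cr$sites$watson_pos, 2L)
  expect_identical(cr$sites$strand, "+")
  # C-CT '-': read is Crick-oriented revcomp, C over Crick C (Watson G at 3)
  crick_read <- reverse_complement("ATCGATT")  # AATCGAT
  cc <- call_read(.raln(pair_tag = "C-CT", watson_pos = 0L,
                        watson_strand = "-", orig_seq = crick_read), ref)
  expect_identical(cc$sites$watson_pos, 3L)
  expect_identical(cc$sites$strand, "-")
  expect_identical(cc$sites$context, "CpG")
  expect_true(cc$sites$methylated)
  # W-GA '+': read G over Watson G informs the '-' strand site
  wg <- call_read(.raln(pair_tag = "W-GA", watson_pos = 0L,
                        orig_seq = "ATCGATT"), ref)
  expect_identical(wg$sites$watson_pos, 3L)
  expect_identical(wg$sites$strand, "-")
  # unmethylated on C-GA: read A over Crick G (Watson C) -> '+' site, unmeth
  cg_read <- chartr("G", "A", reverse_complement("ATCGATT"))  # AATCAAT... G->A
  cg <- call_read(.raln(pair_tag = "C-GA", watson_pos = 0L,
                        watson_strand = "-", orig_seq = cg_read), ref)
  expect_identical(cg$sites$watson_pos, 2L)
  expect_identical(cg$sites$strand, "+")
  expect_false(cg$sites$methylated)
})

test_that("aggregate_sites counts methylated/unmethylated calls per site", {
  sites <- data.frame(
    seq_name = "s", watson_pos = c(5L, 5L, 5L, 9L), strand = "+",
    context = c("CpG", "CpG", "CpG", "CHH"),
    methylated = c(TRUE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  agg <- aggregate_sites(sites)
  expect_identical(nrow(agg), 2L)
  cpg <- agg[agg$watson_pos == 5L, ]
  expect_identical(cpg$n_meth, 2L)
  expect_identical(cpg$n_unmeth, 1L)
  expect_equal(cpg$level, 2 / 3)
  # 3 M + 1 u at one site -> 0.75
  s2 <- data.frame(seq_name = "s", watson_pos = 1L, strand = "+",
                   context = "CpG", methylated = c(TRUE, TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  expect_equal(aggregate_sites(s2)$level, 0.75)
  expect_identical(nrow(aggregate_sites(NULL)), 0L)
})

test_that("write_sam emits valid records and round-trips sites", {
  ref <- reference_genome(c(s = "ATCGATTACG"))
  resolved <- rbind(
    .raln(read_id = "p", pair_tag = "W-CT", watson_pos = 2L, orig_seq = "CGAT"),
    .raln(read_id = "m", pair_tag = "C-CT", watson_pos = 0L,
          watson_strand = "-", orig_seq = reverse_complement("ATCG")))
  calls <- c(p = call_read(resolved[1, ], ref)$calls,
             m = call_read(resolved[2, ], ref)$calls)
  sam <- tempfile(fileext = ".sam")
  write_sam(resolved, calls, ref, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:s\tLN:10$", lines)))
  recs <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_identical(length(recs), 2L)
  minus <- recs[[which(vapply(recs, `[`, character(1), 1L) == "m")]]
  expect_identical(minus[2], "16")
  expect_identical(minus[4], "1")          # POS is 1-based
  expect_identical(minus[10], "ATCG")      # SEQ reverse-complemented back
  plus <- recs[[which(vapply(recs, `[`, character(1), 1L) == "p")]]
  expect_identical(plus[2], "0")
  expect_identical(plus[4], "3")
  expect_true(any(grepl("^ZM:Z:", plus)))
  # empty input -> header-only SAM
  sam0 <- tempfile(fileext = ".sam")
  write_sam(resolved[0, ], character(0), ref, sam0)
  expect_true(all(startsWith(readLines(sam0), "@")))
  # sites reconstructed from the SAM match direct calling
  sfs <- sites_from_sam(sam)
  expect_identical(nrow(sfs), 2L)
  expect_setequal(sfs$watson_pos, c(2L, 3L))
})

test_that("pipeline calls match simulator truth exactly at zero error", {
  ref <- synth_genome(8000, seed = 21)
  pack <- prepare_genome(ref, k = 10)
  cfg <- sim_config(n_reads = 300, read_len = 60, error_rate = 0, seed = 22)
  sim <- simulate_reads(cfg, ref)
  res <- run_pipeline(pack, toy_reads_df(sim$reads$read_id, sim$reads$seq,
                                         sim$reads$qual))
  expect_gt(nrow(res$resolved), 250L)
  tr <- sim$truth
  cache <- methylign:::.context_cache(ref)
  for (i in seq_len(nrow(res$resolved))) {
    r <- res$resolved[i, , drop = FALSE]
    t <- tr[tr$read_id == r$read_id, ]
    tpos <- if (nzchar(t$meth_pos)) as.integer(strsplit(t$meth_pos, ",")[[1]])
            else integer(0)
    tst <- if (nzchar(t$meth_state)) strsplit(t$meth_state, ",")[[1]] == "M"
           else logical(0)
    cr <- call_read(r, ref, cache)
    o <- order(tpos)
    so <- order(cr$sites$watson_pos)
    expect_identical(cr$sites$watson_pos[so], tpos[o])
    expect_identical(cr$sites$methylated[so], tst[o])
    expect_true(all(cr$sites$strand == t$site_strand))
  }
})
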