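# Independent oracles used across the suite. These deliberately avoid the
# package's alignment path: plain byte-level comparison at every offset.

# revcomp/convert written independently of the package (vector ops on chars)
o_revcomp <- function(s) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(m[strsplit(s, "")[[1]]])), collapse = "")
}
o_convert <- function(s, rule) {
  ch <- strsplit(s, "")[[1]]
  if (rule == "CT") ch[ch == "C"] <- "T" else ch[ch == "G"] <- "A"
  paste(ch, collapse = "")
}

# Hamming mismatch count of `read` at every 0-based offset of `gseq`;
# returns data.frame(pos, mm) for offsets with mm <= max_mm.
oracle_scan <- function(read, gseq, max_mm) {
  g <- charToRaw(gseq)
  r <- charToRaw(read)
  L <- length(r)
  n <- length(g) - L + 1L
  if (n < 1L) return(data.frame(pos = integer(0), mm = integer(0)))
  mm <- integer(n)
  base <- seq_len(n)
  for (i in seq_len(L)) mm <- mm + (g[base + i - 1L] != r[i])
  keep <- mm <= max_mm
  data.frame(pos = base[keep] - 1L, mm = mm[keep])
}

# Full-pipeline oracle for one read: brute-force all offsets on all candidate
# conversion pairs, lift Crick coordinates, deduplicate coincident
# (seq, watson_pos, strand) placements across pair tags, then apply the
# uniquely-least-mismatch rule.
oracle_resolve <- function(orig_seq, ref_sequences, max_mm = 4L,
                           library = "non-directional") {
  tags <- if (library == "non-directional")
    c("W-CT", "C-CT", "W-GA", "C-GA") else c("W-CT", "C-CT")
  hits <- NULL
  for (sn in names(ref_sequences)) {
    watson <- ref_sequences[[sn]]
    slen <- nchar(watson)
    gseqs <- list(
      "W-CT" = o_convert(watson, "CT"),
      "W-GA" = o_convert(watson, "GA"),
      "C-CT" = o_convert(o_revcomp(watson), "CT"),
      "C-GA" = o_convert(o_revcomp(watson), "GA"))
    for (tag in tags) {
      conv <- if (tag %in% c("W-CT", "C-CT")) "CT" else "GA"
      sc <- oracle_scan(o_convert(orig_seq, conv), gseqs[[tag]], max_mm)
      if (!nrow(sc)) next
      crick <- tag %in% c("C-CT", "C-GA")
      wpos <- if (crick) slen - sc$pos - nchar(orig_seq) else sc$pos
      hits <- rbind(hits, data.frame(
        tag = tag, seq_name = sn, watson_pos = wpos,
        strand = if (crick) "-" else "+", mm = sc$mm,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits) || !nrow(hits))
    return(list(status = "unmapped"))
  hits <- hits[order(hits$mm, match(hits$tag, c("W-CT", "W-GA", "C-CT", "C-GA"))), ]
  hits <- hits[!duplicated(hits[, c("seq_name", "watson_pos", "strand")]), ]
  best <- min(hits$mm)
  at <- hits[hits$mm == best, , drop = FALSE]
  if (nrow(at) > 1L) return(list(status = "ambiguous"))
  list(status = "resolved", seq_name = at$seq_name, watson_pos = at$watson_pos,
       strand = at$strand, mm = at$mm, tag = at$tag)
}

# small deterministic fixtures -------------------------------------------

toy_reads_df <- function(ids, seqs, quals = NULL) {
  data.frame(read_id = ids, seq = seqs,
             qual = if (is.null(quals)) NA_character_ else quals,
             stringsAsFactors = FALSE)
}

write_fastq_fixture <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}

write_fasta_fixture <- function(ids, seqs, path = tempfile(fileext = ".fa"),
                                width = 0L) {
  lines <- unlist(lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    body <- if (width > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    } else s
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}
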