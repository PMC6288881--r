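# Bisulfite read simulator with truth records, plus evaluation metrics for a
# run against the truth.
#
# Error model: the per-position substitution probability decays exponentially
# along the read, p_i = A * exp(-i / tau) with tau = read_len / 3 and A
# normalized so that mean(p_i) equals the requested mean per-bp error rate.
# Error positions are coupled across error rates: with a fixed seed the same
# uniform draws are thresholded against the scaled profile, so the error set
# at a lower rate is a subset of the set at a higher rate.

#' Generate a synthetic reference genome
#'
#' A random sequence with the requested GC fraction; optionally plants
#' duplicated blocks to create mapping ambiguity. Deterministic for a fixed
#' seed.
#'
#' @param length Sequence length in bases.
#' @param gc GC fraction (default 0.41, mammalian-like).
#' @param repeat_spec Optional list `list(block_len =, n_copies =)`: one
#'   random block is copied to `n_copies - 1` additional random positions.
#' @param seed Integer seed.
#' @param seq_name Name of the single sequence.
#' @return A `ReferenceGenome` with one sequence.
#' @export
synth_genome <- function(length, gc = 0.41, repeat_spec = NULL, seed = 1L,
                         seq_name = "synth1") {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), length, replace = TRUE, prob = probs)
  if (!is.null(repeat_spec)) {
    bl <- repeat_spec$block_len
    nc <- repeat_spec$n_copies
    if (is.null(bl) || is.null(nc) || bl > length || nc < 2L)
      stop("infeasible repeat_spec")
    src <- sample.int(length - bl + 1L, 1L)
    block <- bases[src:(src + bl - 1L)]
    for (i in seq_len(nc - 1L)) {
      dst <- sample.int(length - bl + 1L, 1L)
      bases[dst:(dst + bl - 1L)] <- block
    }
  }
  reference_genome(setNames(paste(bases, collapse = ""), seq_name))
}

#' Simulator configuration
#'
#' @param n_reads Number of reads.
#' @param read_len Read length (default 95).
#' @param library `"non-directional"` (reads from all four bisulfite strand
#'   origins OT/OB/CTOT/CTOB) or `"directional"` (OT/OB only).
#' @param error_rate Mean per-bp substitution error rate.
#' @param conversion_rate Probability that an unmethylated C is read as T.
#' @param p_cpg,p_chg,p_chh Per-context methylation probabilities (defaults
#'   0.7 / 0.02 / 0.02, mammalian-like).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads, read_len = 95L,
                       library = c("non-directional", "directional"),
                       error_rate = 0, conversion_rate = 1.0,
                       p_cpg = 0.7, p_chg = 0.02, p_chh = 0.02, seed = 1L) {
  library <- match.arg(library)
  probs <- c(error_rate, conversion_rate, p_cpg, p_chg, p_chh)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_reads < 1L) stop("n_reads must be >= 1")
  structure(list(n_reads = as.integer(n_reads), read_len = as.integer(read_len),
                 library = library, error_rate = error_rate,
                 conversion_rate = conversion_rate, p_cpg = p_cpg,
                 p_chg = p_chg, p_chh = p_chh, seed = as.integer(seed)),
            class = "sim_config")
}

# positional error profile; returns list(p = per-position prob, qual = Phred+33
# quality string encoding the profile)
.error_profile <- function(read_len, error_rate) {
  i <- 0:(read_len - 1L)
  decay <- exp(-i / (read_len / 3))
  p <- if (error_rate > 0) pmin(error_rate * read_len * decay / sum(decay), 1)
       else rep(0, read_len)
  q <- ifelse(p > 0, pmin(40L, pmax(2L, round(-10 * log10(p)))), 40L)
  list(p = p, qual = intToUtf8(q + 33L))
}

#' Simulate bisulfite-treated reads with truth records
#'
#' Each read takes a uniform random locus and strand-origin class (OT/OB, plus
#' CTOT/CTOB in non-directional mode), draws a truth methylation state for
#' every cytosine of the originating strand by context probability, applies
#' bisulfite conversion to unmethylated cytosines with `conversion_rate`, and
#' finally applies positional substitution errors (see the error model above).
#' Qualities encode the positional error probabilities on the Phred scale.
#'
#' @param cfg A [sim_config()].
#' @param ref A `ReferenceGenome`.
#' @param out_prefix Optional path prefix: writes `<prefix>.fastq` and
#'   `<prefix>.truth.tsv`.
#' @return List with `reads` (data.frame `read_id`, `seq`, `qual`) and `truth`
#'   (data.frame `read_id`, `seq_name`, `watson_pos` (0-based), `strand`
#'   (alignment strand), `class`, `site_strand`, `meth_pos` / `meth_state`
#'   (comma-joined per-cytosine truth)), plus the file paths when written.
#' @export
simulate_reads <- function(cfg, ref, out_prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "ReferenceGenome"))
  L <- cfg$read_len
  if (L > max(ref$lengths)) stop("read_len exceeds every reference sequence")
  set.seed(cfg$seed)

  classes <- if (cfg$library == "non-directional")
    c("OT", "OB", "CTOT", "CTOB") else c("OT", "OB")
  n <- cfg$n_reads
  avail <- pmax(ref$lengths - L + 1L, 0L)
  seq_idx <- sample.int(length(avail), n, replace = TRUE, prob = avail)
  pos <- floor(runif(n) * avail[seq_idx])  # 0-based fragment start
  cls <- sample(classes, n, replace = TRUE)

  prof <- .error_profile(L, cfg$error_rate)
  ctx_cache <- .context_cache(ref)
  p_ctx <- c(CpG = cfg$p_cpg, CHG = cfg$p_chg, CHH = cfg$p_chh)

  frags <- substring(ref$sequences[seq_idx], pos + 1L, pos + L)
  frag_chars <- strsplit(frags, "", fixed = TRUE)

  seqs <- character(n)
  meth_pos <- character(n)
  meth_state <- character(n)
  for (r in seq_len(n)) {
    wc <- frag_chars[[r]]
    cc <- ctx_cache[[seq_idx[r]]]
    watson_origin <- cls[r] %in% c("OT", "CTOT")
    if (watson_origin) {
      strand_chars <- wc
      ci <- which(strand_chars == "C")
      site_pos <- pos[r] + ci - 1L
      ctx <- cc$plus[site_pos + 1L]
    } else {
      strand_chars <- rev(chartr("ACGTN", "TGCAN", wc))
      ci <- which(strand_chars == "C")
      site_pos <- pos[r] + (L - ci)
      ctx <- cc$minus[site_pos + 1L]
    }
    ncyt <- length(ci)
    meth <- runif(ncyt) < p_ctx[ctx]
    convert <- runif(ncyt) < cfg$conversion_rate
    strand_chars[ci[!meth & convert]] <- "T"
    read_chars <- if (cls[r] %in% c("OT", "OB")) strand_chars
                  else rev(chartr("ACGTN", "TGCAN", strand_chars))
    u <- runif(L)
    pick <- sample.int(3L, L, replace = TRUE)
    err <- which(u < prof$p)
    if (length(err)) {
      for (e in err) {
        alt <- setdiff(c("A", "C", "G", "T"), read_chars[e])
        read_chars[e] <- alt[pick[e]]
      }
    }
    seqs[r] <- paste(read_chars, collapse = "")
    meth_pos[r] <- paste(site_pos, collapse = ",")
    meth_state[r] <- paste(ifelse(meth, "M", "U"), collapse = ",")
  }

  aln_strand <- ifelse(cls %in% c("OT", "CTOB"), "+", "-")
  site_strand <- ifelse(cls %in% c("OT", "CTOT"), "+", "-")
  ids <- sprintf("sr%07d", seq_len(n))
  reads <- data.frame(read_id = ids, seq = seqs,
                      qual = rep(prof$qual, n), stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, seq_name = names(ref$lengths)[seq_idx],
                      watson_pos = as.integer(pos), strand = aln_strand,
                      class = cls, site_strand = site_strand,
                      meth_pos = meth_pos, meth_state = meth_state,
                      stringsAsFactors = FALSE)
  out <- list(reads = reads, truth = truth)
  if (!is.null(out_prefix)) {
    fq <- paste0(out_prefix, ".fastq")
    tt <- paste0(out_prefix, ".truth.tsv")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", reads$qual), fq)
    utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    out$fastq_path <- fq
    out$truth_path <- tt
  }
  out
}

# Minimal parse of a methylign/backend SAM for evaluation: mapped primary
# records -> read_id, seq_name, 0-based watson_pos, strand.
.parse_sam_alignments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(read_id = character(0), seq_name = character(0),
                      watson_pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L
  data.frame(
    read_id = vapply(f, `[`, character(1), 1L)[keep],
    seq_name = vapply(f, `[`, character(1), 3L)[keep],
    watson_pos = vapply(f, function(x) as.integer(x[4]), integer(1))[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) == 0L, "+", "-"),
    stringsAsFactors = FALSE)
}

#' Evaluate a run against simulator truth
#'
#' A mapped read is correct iff its (sequence, Watson position, strand) match
#' the truth record within `tolerance` bases (exact by default). Reads
#' discarded as ambiguous are unmapped here, hence false negatives.
#' Following the standard accounting for simulated data: TP = correctly
#' mapped, FP = incorrectly mapped, FN = unmapped; mappability =
#' mapped / all, precision = TP/(TP+FP), sensitivity = TP/(TP+FN),
#' accuracy = TP/(TP+FP+FN).
#'
#' @param sam Path to the SAM produced by the pipeline (or a data.frame with
#'   `read_id`, `seq_name`, `watson_pos`, `strand`).
#' @param truth Path to the simulator truth TSV (or its data.frame).
#' @param tolerance Maximum position deviation counted as correct (default 0).
#' @return An `eval_metrics` list: `TP`, `FP`, `FN`, `n_reads`, `mappability`,
#'   `precision`, `sensitivity`, `accuracy`, `degenerate` (TRUE when nothing
#'   mapped, making precision NaN).
#' @export
evaluate_alignments <- function(sam, truth, tolerance = 0L) {
  aln <- if (is.character(sam)) .parse_sam_alignments(sam) else sam
  tr <- if (is.character(truth))
    utils::read.delim(truth, stringsAsFactors = FALSE) else truth
  unknown <- setdiff(aln$read_id, tr$read_id)
  if (length(unknown))
    stop(sprintf("read id '%s' in SAM is absent from truth", unknown[1]))
  m <- match(aln$read_id, tr$read_id)
  correct <- aln$seq_name == tr$seq_name[m] &
    abs(aln$watson_pos - tr$watson_pos[m]) <= tolerance &
    aln$strand == tr$strand[m]
  n_all <- nrow(tr)
  mapped <- nrow(aln)
  TP <- sum(correct)
  FP <- mapped - TP
  FN <- n_all - mapped
  degenerate <- mapped == 0L
  structure(list(
    TP = TP, FP = FP, FN = FN, n_reads = n_all,
    mappability = mapped / n_all,
    precision = if (degenerate) NaN else TP / (TP + FP),
    sensitivity = TP / (TP + FN),
    accuracy = TP / (TP + FP + FN),
    degenerate = degenerate
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "eval_metrics: n=%d TP=%d FP=%d FN=%d\n  mappability=%.4f precision=%s sensitivity=%.4f accuracy=%.4f\n",
    x$n_reads, x$TP, x$FP, x$FN, x$mappability,
    ifelse(is.nan(x$precision), "NaN", sprintf("%.4f", x$precision)),
    x$sensitivity, x$accuracy))
  invisible(x)
}
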