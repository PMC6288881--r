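# Methylation profiling: compare each resolved read to the ORIGINAL
# (unconverted) reference, call per-base methylation with CpG/CHG/CHH
# context, emit SAM, and aggregate per-site levels.
#
# Call alphabet (Bismark-style): Z/z CpG, X/x CHG, H/h CHH; uppercase =
# methylated, lowercase = unmethylated, '.' = no cytosine information.

CONTEXT_LETTER <- c(CpG = "Z", CHG = "X", CHH = "H")

# Per-sequence context lookup tables, computed once per staged reference:
# plus[p] is the context of a Watson-strand cytosine at 0-based p (NA if the
# base is not C); minus[p] likewise for Crick-strand cytosines (Watson G).
# Positions too close to the sequence end default to CHH.
.context_cache <- function(ref) {
  lapply(ref$sequences, function(seq) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(b)
    nx1 <- c(b[-1], "N")
    nx2 <- c(b[-(1:2)], "N", "N")
    pv1 <- c("N", chartr("ACGTN", "TGCAN", b[-n]))
    pv2 <- c("N", "N", chartr("ACGTN", "TGCAN", b[-c(n - 1L, n)]))
    plus <- ifelse(b != "C", NA_character_,
                   ifelse(nx1 == "G", "CpG", ifelse(nx2 == "G", "CHG", "CHH")))
    minus <- ifelse(b != "G", NA_character_,
                    ifelse(pv1 == "G", "CpG", ifelse(pv2 == "G", "CHG", "CHH")))
    list(bases = b, plus = plus, minus = minus)
  })
}

#' Classify the sequence context of a cytosine
#'
#' Uses the site's own strand, 5'-to-3': `CG*` is CpG, `C(non-G)G` is CHG,
#' anything else CHH. A site within two bases of the sequence end whose
#' context is therefore incomplete is classified CHH by convention and
#' flagged via the `"incomplete"` attribute.
#'
#' @param ref A `ReferenceGenome`.
#' @param seq_name Sequence name.
#' @param watson_pos 0-based Watson position. Must hold C on the given strand
#'   (i.e. a Watson C for `"+"`, a Watson G for `"-"`).
#' @param strand `"+"` or `"-"`.
#' @return `"CpG"`, `"CHG"` or `"CHH"`, with attribute `incomplete = TRUE`
#'   when the downstream context ran off the sequence end.
#' @export
classify_context <- function(ref, seq_name, watson_pos, strand) {
  seq <- ref$sequences[[seq_name]]
  n <- nchar(seq)
  if (watson_pos < 0L || watson_pos >= n) stop("position out of range")
  base <- substr(seq, watson_pos + 1L, watson_pos + 1L)
  if (strand == "+") {
    if (base != "C") stop("position is not a cytosine on the + strand")
    down <- c(if (watson_pos + 1L < n) substr(seq, watson_pos + 2L, watson_pos + 2L),
              if (watson_pos + 2L < n) substr(seq, watson_pos + 3L, watson_pos + 3L))
  } else if (strand == "-") {
    if (base != "G") stop("position is not a cytosine on the - strand")
    down <- chartr("ACGTN", "TGCAN",
                   c(if (watson_pos >= 1L) substr(seq, watson_pos, watson_pos),
                     if (watson_pos >= 2L) substr(seq, watson_pos - 1L, watson_pos - 1L)))
  } else stop("strand must be '+' or '-'")
  incomplete <- length(down) < 2L
  ctx <- if (length(down) >= 1L && down[1] == "G") "CpG"
         else if (length(down) >= 2L && down[2] == "G") "CHG"
         else "CHH"
  if (incomplete && ctx != "CpG") {
    ctx <- "CHH"
    attr(ctx, "incomplete") <- TRUE
  }
  ctx
}

#' Call per-base methylation for one resolved read
#'
#' CT-type alignments (`W-CT`, `C-CT`) carry cytosine information on the
#' read's own strand: at every reference cytosine of that strand, read C means
#' methylated and read T unmethylated. GA-type alignments (`W-GA`, `C-GA`)
#' are complement-strand reads and carry the information as G/A over the
#' opposite strand's cytosines (read G methylated, read A unmethylated). Any
#' other read base (a sequencing error) yields no call at that position.
#'
#' @param aln One-row resolved alignment (see [resolve_hits()]) that also
#'   carries `orig_seq`, the read as sequenced.
#' @param ref A `ReferenceGenome`.
#' @param cache Optional precomputed context cache (internal; computed from
#'   `ref` when absent).
#' @return List with `read_id`, `calls` (string aligned to the read as
#'   sequenced) and `sites`: data.frame `seq_name`, `watson_pos`, `strand`,
#'   `context`, `methylated` (one row per informative call).
#' @export
call_read <- function(aln, ref, cache = NULL) {
  if (is.null(cache)) cache <- .context_cache(ref)
  cc <- cache[[aln$seq_name]]
  L <- aln$read_len
  p0 <- aln$watson_pos
  if (p0 < 0L || p0 + L > length(cc$bases))
    stop("alignment coordinates exceed reference sequence")
  read <- strsplit(aln$orig_seq, "", fixed = TRUE)[[1]]
  if (length(read) != L) stop("orig_seq length does not match read_len")

  plus_aligned <- aln$watson_strand == "+"
  ct_type <- aln$pair_tag %in% c("W-CT", "C-CT")
  # genome offsets (0-based within sequence) covered by the read, in read order
  gpos <- if (plus_aligned) p0 + 0:(L - 1L) else p0 + (L - 1L):0
  # the strand whose cytosines this read informs
  site_strand <- if (ct_type == plus_aligned) "+" else "-"
  ctx_vec <- if (site_strand == "+") cc$plus else cc$minus
  ctx <- ctx_vec[gpos + 1L]
  informative <- !is.na(ctx)
  meth_char <- if (ct_type) "C" else "G"
  unmeth_char <- if (ct_type) "T" else "A"

  calls <- rep(".", L)
  idx <- which(informative)
  state <- rep(NA, L)
  state[idx][read[idx] == meth_char] <- TRUE
  state[idx][read[idx] == unmeth_char] <- FALSE
  has_call <- !is.na(state)
  letter <- CONTEXT_LETTER[ctx[has_call]]
  calls[has_call] <- ifelse(state[has_call], letter, tolower(letter))

  sites <- data.frame(
    seq_name = rep(aln$seq_name, sum(has_call)),
    watson_pos = gpos[has_call],
    strand = rep(site_strand, sum(has_call)),
    context = unname(ctx[has_call]),
    methylated = state[has_call],
    stringsAsFactors = FALSE
  )
  list(read_id = aln$read_id, calls = paste(calls, collapse = ""),
       sites = sites)
}

#' Aggregate per-read calls into per-site methylation counts
#'
#' @param sites data.frame of informative calls as produced by [call_read()]
#'   (rows from many reads concatenated).
#' @return data.frame with one row per (seq_name, watson_pos, strand):
#'   `context`, `n_meth`, `n_unmeth`, `level = n_meth / (n_meth + n_unmeth)`,
#'   ordered by sequence, position, strand. Positions with no calls are
#'   absent.
#' @export
aggregate_sites <- function(sites) {
  empty <- data.frame(seq_name = character(0), watson_pos = integer(0),
                      strand = character(0), context = character(0),
                      n_meth = integer(0), n_unmeth = integer(0),
                      level = numeric(0), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  dt <- data.table::as.data.table(sites)
  agg <- dt[, .(context = context[1L], n_meth = sum(methylated),
                n_unmeth = sum(!methylated)),
            by = .(seq_name, watson_pos, strand)]
  agg[, level := n_meth / (n_meth + n_unmeth)]
  data.table::setorder(agg, seq_name, watson_pos, strand)
  as.data.frame(agg[, .(seq_name, watson_pos, strand, context, n_meth,
                        n_unmeth, level)])
}

#' Write the per-site methylation report
#'
#' Tab-separated, bedGraph-adjacent: `seq`, 1-based `pos`, `strand`,
#' `context`, `n_meth`, `n_unmeth`, `level`.
#'
#' @param site_counts Output of [aggregate_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(site_counts, path) {
  out <- data.frame(seq = site_counts$seq_name, pos = site_counts$watson_pos + 1L,
                    strand = site_counts$strand, context = site_counts$context,
                    n_meth = site_counts$n_meth, n_unmeth = site_counts$n_unmeth,
                    level = site_counts$level, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write resolved alignments with methylation calls to SAM
#'
#' Emits `@HD`/`@SQ` headers from the reference lengths and one record per
#' resolved read: FLAG 0/16 by Watson strand, 1-based POS, MAPQ 255, CIGAR
#' `<len>M`, SEQ reverse-complemented for minus-strand records per SAM
#' convention, and tags `NM:i` (converted-space mismatches), `ZC:Z`
#' (conversion pair tag) and `ZM:Z` (call string, oriented as sequenced).
#' Records are sorted by (sequence, position, read id).
#'
#' @param resolved Resolved alignments with `orig_seq` column.
#' @param calls Named character vector of call strings keyed by read id.
#' @param ref A `ReferenceGenome`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(resolved, calls, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$lengths),
                      unname(ref$lengths)),
              sprintf("@PG\tID:methylign\tPN:methylign\tVN:%s",
                      as.character(utils::packageVersion("methylign"))))
  if (nrow(resolved) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(match(resolved$seq_name, names(ref$lengths)),
               resolved$watson_pos, resolved$read_id)
  r <- resolved[ord, , drop = FALSE]
  minus <- r$watson_strand == "-"
  seq_out <- r$orig_seq
  seq_out[minus] <- vapply(seq_out[minus], reverse_complement, character(1))
  recs <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tZC:Z:%s\tZM:Z:%s",
    r$read_id, ifelse(minus, 16L, 0L), r$seq_name, r$watson_pos + 1L,
    r$read_len, seq_out, r$mismatches, r$pair_tag,
    unname(calls[r$read_id]))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Rebuild per-site counts from a methylign SAM
#'
#' Reads the `ZC`/`ZM` tags back and reconstructs the informative sites of
#' every record, so a site report can be produced from a SAM alone.
#'
#' @param path SAM produced by [write_sam()].
#' @return data.frame of per-call sites (same layout as [call_read()] sites).
#' @export
sites_from_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    tags <- f[-(1:11)]
    zc <- sub("^ZC:Z:", "", grep("^ZC:Z:", tags, value = TRUE)[1])
    zm <- sub("^ZM:Z:", "", grep("^ZM:Z:", tags, value = TRUE)[1])
    if (is.na(zc) || is.na(zm))
      stop(sprintf("SAM record %s lacks ZC/ZM tags", f[1]))
    flag <- as.integer(f[2])
    p0 <- as.integer(f[4]) - 1L
    L <- nchar(zm)
    plus_aligned <- bitwAnd(flag, 16L) == 0L
    ct_type <- zc %in% c("W-CT", "C-CT")
    gpos <- if (plus_aligned) p0 + 0:(L - 1L) else p0 + (L - 1L):0
    cv <- strsplit(zm, "", fixed = TRUE)[[1]]
    has <- cv != "."
    if (!any(has)) next
    ctx <- setNames(names(CONTEXT_LETTER), CONTEXT_LETTER)[toupper(cv[has])]
    out[[i]] <- data.frame(
      seq_name = f[3], watson_pos = gpos[has],
      strand = if (ct_type == plus_aligned) "+" else "-",
      context = unname(ctx), methylated = cv[has] %in% CONTEXT_LETTER,
      stringsAsFactors = FALSE)
  }
  as.data.frame(data.table::rbindlist(out))
}
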