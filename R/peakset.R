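#' Construct a peak set
#'
#' A `peak_set` is the universe of candidate binding/accessibility sites: a
#' sorted table of genomic intervals in 0-based half-open (BED) coordinates,
#' with optional per-interval summit offsets (relative to `start`, ENCODE
#' narrowPeak dialect) and -log10 q-value scores.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end`.
#' @param site_id unique identifiers; defaults to `peak_1 ... peak_n`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param summit optional integer offset of the signal maximum from `start`,
#'   in `[0, end - start)`; `NA` when unknown.
#' @param score optional numeric score (-log10 q-value); `NA` when unknown.
#' @return a `peak_set` data frame sorted by (chrom, start).
#' @examples
#' peak_set(c("chr1", "chr1"), c(100L, 900L), c(600L, 1400L))
#' @export
peak_set <- function(chrom, start, end, site_id = NULL, strand = NULL,
                     summit = NULL, score = NULL) {
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (!is.null(strand) && length(strand) == 1L) strand <- rep(strand, n)
  start <- as.integer(start)
  end <- as.integer(end)
  site_id <- as.character(site_id %||% if (n) paste0("peak_", seq_len(n)) else character())
  strand <- as.character(strand %||% rep(".", n))
  summit <- as.integer(summit %||% rep(NA_integer_, n))
  score <- as.numeric(score %||% rep(NA_real_, n))
  assert_that(all(lengths(list(start, end, site_id, strand, summit, score)) == n),
              "peak_set fields must have equal length")
  if (n) {
    assert_that(all(nzchar(chrom)), "chrom names must be non-empty")
    assert_that(all(start >= 0L), "start must be >= 0")
    assert_that(all(end > start), "end must be > start for every interval")
    assert_that(!anyDuplicated(site_id), "site_ids must be unique")
    assert_that(all(strand %in% c("+", "-", ".")), "strand must be +, - or .")
    ok <- is.na(summit) | (summit >= 0L & summit < end - start)
    assert_that(all(ok), "summit offsets must lie within [0, end - start)")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   site_id = site_id, strand = strand, summit = summit,
                   score = score, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set with %d intervals on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

as_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    site_id = peaks$site_id)
}

# Peak center: summit-anchored when the summit is known (MACS2 practice),
# otherwise the integer midpoint.
peak_center <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  ifelse(is.na(peaks$summit), mid, peaks$start + peaks$summit)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

parse_int <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    bad <- lineno[is.na(v)][1]
    stopf("%s: line %d: malformed %s field", path, bad, what)
  }
  v
}

#' Read a peak set from BED or narrowPeak
#'
#' Parses BED (3-6 columns) or ENCODE narrowPeak (10 columns). The
#' narrowPeak q-value column (9) becomes `score` and the point-source
#' column (10) becomes `summit` (offset from start, -1 meaning unknown).
#' Malformed lines are rejected with their line number, never skipped.
#'
#' @param path file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(peak_set(character(), integer(), integer()))
  fields <- split_fields(lines)
  nf <- lengths(fields)
  lineno <- seq_along(lines)
  if (format == "narrowPeak") {
    if (any(nf != 10L)) {
      stopf("%s: line %d: expected 10 narrowPeak columns, found %d",
            path, lineno[nf != 10L][1], nf[nf != 10L][1])
    }
  } else if (any(nf < 3L)) {
    stopf("%s: line %d: expected >= 3 BED columns", path, lineno[nf < 3L][1])
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  chrom <- col(1)
  start <- parse_int(col(2), path, lineno, "start")
  end <- parse_int(col(3), path, lineno, "end")
  if (any(end <= start)) {
    stopf("%s: line %d: end <= start", path, lineno[end <= start][1])
  }
  name <- if (max(nf) >= 4L) col(4) else paste0("peak_", lineno)
  strand <- if (max(nf) >= 6L) col(6) else rep(".", length(lines))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  if (format == "narrowPeak") {
    score <- suppressWarnings(as.numeric(col(9)))
    score[!is.na(score) & score < 0] <- NA_real_
    summit <- parse_int(col(10), path, lineno, "summit")
    summit[summit < 0L] <- NA_integer_
    bad <- !is.na(summit) & summit >= end - start
    if (any(bad)) stopf("%s: line %d: summit outside interval", path, lineno[bad][1])
  } else {
    score <- if (max(nf) >= 5L) suppressWarnings(as.numeric(col(5))) else rep(NA_real_, length(lines))
    summit <- NULL
  }
  peak_set(chrom, start, end, site_id = name, strand = strand,
           summit = summit, score = score)
}

#' Write a peak set to BED or narrowPeak
#'
#' Round-trips coordinates, identifiers, scores and (for narrowPeak)
#' summits bit-exactly through [read_peaks()]. Writing summit-carrying
#' peaks as BED drops the summits with a warning, since BED has no summit
#' column.
#'
#' @param peaks a [peak_set()].
#' @param path output file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  score_chr <- ifelse(is.na(peaks$score), if (format == "bed") "0" else "-1",
                      format(peaks$score, trim = TRUE, scientific = FALSE, digits = 15))
  if (format == "bed") {
    if (any(!is.na(peaks$summit))) {
      warnf("BED has no summit column; %d summit(s) dropped", sum(!is.na(peaks$summit)))
    }
    lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$site_id,
                   score_chr, peaks$strand, sep = "\t")
  } else {
    summit_chr <- ifelse(is.na(peaks$summit), "-1", as.character(peaks$summit))
    lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$site_id,
                   "0", peaks$strand, "0", "-1", score_chr, summit_chr, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Re-center peaks to a fixed width
#'
#' Replaces each interval by a fixed-width window around its center
#' (summit-anchored when available, midpoint otherwise), mirroring
#' fixed-width differential-binding quantification. Windows running off the
#' left edge are clipped at 0 and flagged in the `clipped` column.
#'
#' @param peaks a [peak_set()].
#' @param width positive integer window width in bp.
#' @return a `peak_set` with an extra logical `clipped` column; summits are
#'   re-expressed relative to the new starts.
#' @export
recenter_fixed_width <- function(peaks, width) {
  assert_that(length(width) == 1 && width > 0, "width must be a positive integer")
  width <- as.integer(width)
  if (!nrow(peaks)) {
    out <- peaks
    out$clipped <- logical(0)
    return(out)
  }
  center <- peak_center(peaks)
  new_start <- center - width %/% 2L
  new_end <- new_start + width
  clipped <- new_start < 0L
  new_start[clipped] <- 0L
  out <- peak_set(peaks$chrom, new_start, new_end, site_id = peaks$site_id,
                  strand = peaks$strand,
                  summit = pmin(center - new_start, new_end - new_start - 1L),
                  score = peaks$score)
  out$clipped <- clipped[match(out$site_id, peaks$site_id)]
  out
}

#' Remove peaks overlapping a blacklist
#'
#' Discards every peak with at least 1 bp of overlap with any blacklist
#' interval (half-open adjacency is not overlap). Idempotent.
#'
#' @param peaks,blacklist [peak_set()] objects.
#' @return the filtered `peak_set`; the number removed is reported.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (!nrow(peaks) || !nrow(blacklist)) return(peaks)
  hits <- GenomicRanges::countOverlaps(as_granges(peaks), as_granges(blacklist))
  removed <- sum(hits > 0)
  if (removed) message(sprintf("subtract_blacklist: removed %d of %d peaks", removed, nrow(peaks)))
  out <- peaks[hits == 0L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Read a minimal gene model table
#'
#' Tab-delimited with columns `gene_id`, `chrom`, `tss`, `strand`
#' (header optional but recommended). TSS positions are 0-based.
#'
#' @param path file path.
#' @return data frame with columns gene_id, chrom, tss, strand.
#' @export
read_genes <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  first <- readLines(path, n = 1)
  header <- grepl("gene_id", first, fixed = TRUE)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("gene_id", "chrom", "tss", "strand"))
  }
  gene_model(df$gene_id, df$chrom, df$tss, df$strand)
}

#' Construct a gene model table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param tss 0-based transcription start positions, `>= 0`.
#' @param strand `"+"` or `"-"`.
#' @return data frame of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, tss, strand = NULL) {
  n <- length(gene_id)
  strand <- strand %||% rep("+", n)
  tss <- as.integer(tss)
  assert_that(!anyDuplicated(gene_id), "gene_ids must be unique")
  assert_that(all(tss >= 0L), "tss must be >= 0")
  assert_that(all(strand %in% c("+", "-")), "gene strand must be + or -")
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = tss, strand = as.character(strand), stringsAsFactors = FALSE)
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Write a gene model table
#' @param genes a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate peaks with their nearest TSS
#'
#' Assigns each peak to the gene whose TSS minimizes the absolute
#' peak-center-to-TSS distance on the same chromosome. The signed distance
#' is `center - tss` in genomic coordinates (strand-agnostic); ties are
#' broken toward the lexicographically smaller gene_id. Sites more than
#' `distal_bp` from any TSS are `distal`, others `promoter_proximal`;
#' peaks on chromosomes without genes are `unannotated` (gene_id `NA`).
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_model()]; must be non-empty.
#' @param distal_bp distance threshold in bp separating promoter-proximal
#'   from distal sites (default 2000).
#' @return data frame: site_id, gene_id, distance, locale.
#' @export
nearest_tss <- function(peaks, genes, distal_bp = 2000) {
  assert_that(nrow(genes) > 0, "genes must be non-empty")
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  center <- peak_center(peaks)
  for (chr in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    tss <- g$tss
    # candidate neighbours around each center via findInterval, then pick
    # the minimal |distance| with lexicographic gene_id tie-break
    idx <- findInterval(center[pk], tss)
    for (k in seq_along(pk)) {
      i <- pk[k]
      cand <- unique(pmin(pmax(idx[k] + c(-1L, 0L, 1L, 2L), 1L), length(tss)))
      d <- center[i] - tss[cand]
      best <- which(abs(d) == min(abs(d)))
      if (length(best) > 1) best <- best[order(g$gene_id[cand[best]])][1]
      gene_id[i] <- g$gene_id[cand[best]]
      distance[i] <- d[best]
    }
  }
  locale <- ifelse(is.na(gene_id), "unannotated",
                   ifelse(abs(distance) > distal_bp, "distal", "promoter_proximal"))
  data.frame(site_id = peaks$site_id, gene_id = gene_id,
             distance = distance, locale = locale, stringsAsFactors = FALSE)
}

#' Overlap bookkeeping between two peak sets
#'
#' A site in `a` is shared iff it overlaps any site in `b` by at least
#' 1 bp; counts are reported from both sides (the two shared counts can
#' differ when intervals merge many-to-one).
#'
#' @param a,b [peak_set()] objects.
#' @return list with `shared_a`, `shared_b`, `a_only`, `b_only`.
#' @export
overlap_sets <- function(a, b) {
  if (!nrow(a) || !nrow(b)) {
    return(list(shared_a = 0L, shared_b = 0L, a_only = nrow(a), b_only = nrow(b)))
  }
  ga <- as_granges(a)
  gb <- as_granges(b)
  # differing chromosome universes between the two sets are expected
  sa <- sum(suppressWarnings(GenomicRanges::countOverlaps(ga, gb)) > 0L)
  sb <- sum(suppressWarnings(GenomicRanges::countOverlaps(gb, ga)) > 0L)
  list(shared_a = sa, shared_b = sb, a_only = nrow(a) - sa, b_only = nrow(b) - sb)
}

#' Write a bedGraph track
#'
#' @param peaks a [peak_set()] supplying intervals.
#' @param values numeric vector, one value per interval.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(peaks, values, path) {
  assert_that(length(values) == nrow(peaks), "one value per interval required")
  writeLines(paste(peaks$chrom, peaks$start, peaks$end,
                   format(values, trim = TRUE, scientific = FALSE, digits = 10),
                   sep = "\t"), path)
  invisible(path)
}
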