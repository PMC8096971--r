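#' Construct a motif model
#'
#' A motif is a 4 x L position-probability matrix (rows A, C, G, T) with a
#' background base composition and a log-odds score threshold in bits.
#' The default threshold is 80% of the maximum attainable score, a relative
#' rule that adapts across motif lengths.
#'
#' @param motif_id identifier.
#' @param ppm numeric 4 x L matrix, each column summing to 1 (tolerance
#'   1e-9); rownames A, C, G, T; L >= 4.
#' @param background length-4 base frequencies summing to 1 (default
#'   uniform).
#' @param score_threshold log-odds threshold in bits; `NULL` for the 80%
#'   rule.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(motif_id, ppm, background = rep(0.25, 4),
                        score_threshold = NULL) {
  ppm <- as.matrix(ppm)
  assert_that(nrow(ppm) == 4, "ppm must have 4 rows (A, C, G, T)")
  assert_that(ncol(ppm) >= 4, "motif length must be >= 4")
  assert_that(all(abs(colSums(ppm) - 1) <= 1e-9), "ppm columns must sum to 1")
  assert_that(abs(sum(background) - 1) <= 1e-9, "background must sum to 1")
  rownames(ppm) <- c("A", "C", "G", "T")
  logodds <- log2(ppm / background)
  max_score <- sum(apply(logodds, 2, max))
  structure(list(motif_id = motif_id, ppm = ppm, background = background,
                 logodds = logodds, max_score = max_score,
                 score_threshold = score_threshold %||% (0.8 * max_score)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s: length %d, max score %.2f bits, threshold %.2f\n",
              x$motif_id, ncol(x$ppm), x$max_score, x$score_threshold))
  invisible(x)
}

#' Motif length
#' @param motif a [motif_model()].
#' @return integer number of columns.
#' @export
motif_length <- function(motif) ncol(motif$ppm)

#' Consensus sequence of a motif
#'
#' The maximum-probability base at each position.
#' @param motif a [motif_model()].
#' @return character string of length L.
#' @export
consensus_seq <- function(motif) {
  paste(rownames(motif$ppm)[apply(motif$ppm, 2, which.max)], collapse = "")
}

#' Read / write motif position-probability matrices
#'
#' Minimal tabular format: a `>motif_id` header line followed by four
#' whitespace-delimited rows labeled `A:`, `C:`, `G:`, `T:`. Several motifs
#' may be concatenated in one file.
#'
#' @param path file path.
#' @return list of [motif_model()] objects named by motif_id.
#' @export
read_motifs <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  assert_that(length(heads) > 0, "%s: no >motif_id header found", path)
  out <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1):(if (i < length(heads)) heads[i + 1] - 1 else length(lines))]
    assert_that(length(block) == 4, "%s: motif %s must have 4 base rows", path, id)
    rows <- lapply(block, function(l) {
      parts <- strsplit(l, "[:[:space:]]+")[[1]]
      list(base = parts[1], probs = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    assert_that(setequal(bases, c("A", "C", "G", "T")),
                "%s: motif %s rows must be labeled A, C, G, T", path, id)
    ppm <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
      rows[[which(bases == b)]]$probs
    }))
    out[[id]] <- motif_model(id, ppm)
  }
  out
}

#' @rdname read_motifs
#' @param motifs list of [motif_model()] objects.
#' @export
write_motifs <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$motif_id),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, ": ", paste(format(m$ppm[b, ], digits = 15), collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled partner-factor motifs
#'
#' Loads the position-probability matrices shipped with the package for the
#' homeodomain (NKX), TEAD, CEBP, CTCF, FOXA, AP-1 and ELF motif families.
#' These are synthetic, consensus-dominated PPMs in the package's tabular
#' format, suitable for planted-motif simulations and known-motif scans.
#'
#' @return named list of [motif_model()] objects.
#' @export
bundled_motifs <- function() {
  read_motifs(system.file("extdata", "motifs", "partner_motifs.txt",
                          package = "bindfate", mustWork = TRUE))
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_seq <- function(seq) {
  v <- DNA_CODE[strsplit(toupper(seq), "")[[1]]]
  v[is.na(v)] <- 5L  # N and other ambiguity codes
  v
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

scan_one_strand <- function(codes, logodds) {
  L <- ncol(logodds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  lo <- rbind(logodds, rep(-Inf, L))  # row 5 scores N as -Inf
  n_off <- n - L + 1L
  scores <- numeric(n_off)
  for (j in seq_len(L)) {
    scores <- scores + lo[cbind(codes[j:(j + n_off - 1L)], j)]
  }
  scores
}

#' Scan a sequence with a PWM
#'
#' Scores every offset of `seq` on both strands with the motif's log-odds
#' matrix (sum over columns of `log2(ppm/background)`; positions containing
#' N score -Inf) and returns offsets meeting the motif's score threshold.
#' Minus-strand hits are reported by the 0-based start of the matched
#' window on the forward sequence. Hits are ordered by (offset, strand).
#'
#' @param seq nucleotide string over A, C, G, T, N.
#' @param motif a [motif_model()].
#' @param site_id identifier recorded with the hits (default `"seq"`).
#' @return data frame: site_id, motif_id, offset, strand, score.
#' @export
scan_pwm <- function(seq, motif, site_id = "seq") {
  L <- motif_length(motif)
  codes <- encode_seq(seq)
  fwd <- scan_one_strand(codes, motif$logodds)
  rc_codes <- encode_seq(revcomp(seq))
  rev_scores <- scan_one_strand(rc_codes, motif$logodds)
  # offset o' on the reverse complement covers forward window starting at
  # n - L - o' (0-based)
  n <- length(codes)
  hits <- list()
  f_off <- which(fwd >= motif$score_threshold) - 1L
  if (length(f_off)) {
    hits[[1]] <- data.frame(offset = f_off, strand = "+",
                            score = fwd[f_off + 1L], stringsAsFactors = FALSE)
  }
  r_off <- which(rev_scores >= motif$score_threshold) - 1L
  if (length(r_off)) {
    hits[[2]] <- data.frame(offset = n - L - r_off, strand = "-",
                            score = rev_scores[r_off + 1L], stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(), strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(site_id = rep(site_id, nrow(out)),
                   motif_id = rep(motif$motif_id, nrow(out)),
                   stringsAsFactors = FALSE), out)
}

#' Scan many site sequences with one or more motifs
#'
#' @param seqs named character vector of site sequences (names are
#'   site_ids).
#' @param motifs a [motif_model()] or list of them.
#' @return combined hit table as in [scan_pwm()].
#' @export
scan_sites <- function(seqs, motifs) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  assert_that(!is.null(names(seqs)), "seqs must be named by site_id")
  out <- list()
  for (m in motifs) {
    for (i in seq_along(seqs)) {
      h <- scan_pwm(seqs[[i]], m, site_id = names(seqs)[i])
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) {
    return(data.frame(site_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment by upper-tail binomial test
#'
#' Fractions are the proportion of sites with at least one hit. The fold is
#' target over background fraction; the p-value is the upper cumulative
#' binomial tail of observing at least the target hit count among the
#' target sites with success probability equal to the background fraction.
#' A zero background fraction is floored at `1 / (2 * n_background)` for
#' the test and the fold is reported as infinite.
#'
#' @param target_seqs,background_seqs named character vectors of site
#'   sequences (non-empty).
#' @param motif a [motif_model()].
#' @return data frame (one row): motif_id, target_fraction,
#'   background_fraction, fold, pvalue, n_target, n_background.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, motif) {
  assert_that(length(target_seqs) > 0 && length(background_seqs) > 0,
              "both site sets must be non-empty")
  has_hit <- function(seqs) {
    vapply(seq_along(seqs), function(i) {
      nrow(scan_pwm(seqs[[i]], motif, site_id = names(seqs)[i] %||% "s")) > 0
    }, logical(1))
  }
  k <- sum(has_hit(target_seqs))
  n <- length(target_seqs)
  tf <- k / n
  bf <- mean(has_hit(background_seqs))
  p_bg <- if (bf > 0) bf else 1 / (2 * length(background_seqs))
  data.frame(motif_id = motif$motif_id, target_fraction = tf,
             background_fraction = bf,
             fold = enrichment_fold(tf, bf),
             pvalue = stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE),
             n_target = n, n_background = length(background_seqs),
             stringsAsFactors = FALSE)
}

#' Enrichment fold from two fractions
#'
#' @param target_fraction,background_fraction fractions of sites carrying
#'   the motif.
#' @return `target_fraction / background_fraction` (`Inf` when the
#'   background fraction is zero).
#' @examples
#' enrichment_fold(0.60, 0.017) # ~35.3-fold
#' @export
enrichment_fold <- function(target_fraction, background_fraction) {
  ifelse(background_fraction > 0, target_fraction / background_fraction, Inf)
}

#' Fraction of sites carrying a motif, per site set
#'
#' @param site_sets named list of site_id vectors.
#' @param hits hit table from [scan_sites()].
#' @param motif_id motif to count.
#' @return data frame: set, fraction, n_sites. Empty sets yield `NA` with a
#'   warning.
#' @export
cooccurrence_fraction <- function(site_sets, hits, motif_id) {
  with_hit <- unique(hits$site_id[hits$motif_id == motif_id])
  rows <- lapply(names(site_sets), function(nm) {
    ids <- site_sets[[nm]]
    if (!length(ids)) {
      warnf("site set '%s' is empty; fraction undefined", nm)
      return(data.frame(set = nm, fraction = NA_real_, n_sites = 0L,
                        stringsAsFactors = FALSE))
    }
    data.frame(set = nm, fraction = mean(ids %in% with_hit),
               n_sites = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distance between two motifs within sites
#'
#' For every site carrying at least one hit of each motif, the distance is
#' the minimum over hit pairs of the absolute difference of hit centers
#' (center = offset + floor(L/2)); the set mean over contributing sites is
#' reported with its n. Distances are center-to-center by declared
#' convention.
#'
#' @param hits hit table from [scan_sites()].
#' @param motif_a,motif_b [motif_model()] objects.
#' @return list with `per_site` (data frame site_id, distance) and
#'   `mean_distance`, `n_sites`.
#' @export
motif_spacing <- function(hits, motif_a, motif_b) {
  ha <- hits[hits$motif_id == motif_a$motif_id, , drop = FALSE]
  hb <- hits[hits$motif_id == motif_b$motif_id, , drop = FALSE]
  ca <- ha$offset + motif_length(motif_a) %/% 2L
  cb <- hb$offset + motif_length(motif_b) %/% 2L
  shared <- intersect(unique(ha$site_id), unique(hb$site_id))
  dist <- vapply(shared, function(s) {
    da <- ca[ha$site_id == s]
    db <- cb[hb$site_id == s]
    min(abs(outer(da, db, "-")))
  }, numeric(1))
  list(per_site = data.frame(site_id = shared, distance = as.integer(dist),
                             stringsAsFactors = FALSE),
       mean_distance = if (length(dist)) mean(dist) else NA_real_,
       n_sites = length(shared))
}

#' Read / write site sequences as FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences keyed by site_id.
#' @export
read_site_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_site_fasta
#' @param seqs named character vector of sequences.
#' @export
write_site_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
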