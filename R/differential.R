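#' Build a fixed-width consensus peak set from several peak sets
#'
#' Peaks from all sets are merged by single-linkage on >= 1 bp overlap;
#' merged clusters supported by at least `min_support` distinct input sets
#' are kept and re-centered to `width` bp on the center (summit-aware) of
#' their maximum-score member. New stable site_ids are assigned in
#' (chrom, start) order.
#'
#' @param peaksets list of [peak_set()] objects.
#' @param min_support minimum number of distinct sets a cluster must touch.
#' @param width fixed output width in bp.
#' @return a `peak_set` of consensus sites.
#' @export
consensus_peakset <- function(peaksets, min_support = 1, width = 500) {
  assert_that(length(peaksets) >= 1, "need at least one peak set")
  assert_that(min_support <= length(peaksets),
              "min_support cannot exceed the number of peak sets")
  all_df <- do.call(rbind, lapply(seq_along(peaksets), function(i) {
    p <- as.data.frame(peaksets[[i]])
    if (nrow(p)) p$set_index <- i
    p
  }))
  if (is.null(all_df) || !nrow(all_df)) return(peak_set(character(), integer(), integer()))
  gr <- GenomicRanges::GRanges(all_df$chrom,
                               IRanges::IRanges(all_df$start + 1L, all_df$end))
  merged <- GenomicRanges::reduce(gr)
  member_of <- GenomicRanges::findOverlaps(gr, merged, select = "first")
  support <- tapply(all_df$set_index, member_of, function(s) length(unique(s)))
  keep <- as.integer(names(support))[support >= min_support]
  if (!length(keep)) return(peak_set(character(), integer(), integer()))
  score_key <- ifelse(is.na(all_df$score), -Inf, all_df$score)
  centers <- integer(length(keep))
  chroms <- character(length(keep))
  center_all <- peak_center(all_df)
  for (k in seq_along(keep)) {
    members <- which(member_of == keep[k])
    best <- members[order(-score_key[members], members)][1]
    centers[k] <- center_all[best]
    chroms[k] <- all_df$chrom[best]
  }
  start <- pmax(centers - width %/% 2L, 0L)
  end <- (centers - width %/% 2L) + width
  ord <- order(chroms, start)
  peak_set(chroms[ord], start[ord], end[ord],
           site_id = sprintf("site_%05d", seq_along(keep)),
           summit = pmin(centers[ord] - start[ord], end[ord] - start[ord] - 1L))
}

#' Moderated two-sample differential binding test
#'
#' Tests each site for differential signal between two sample groups on
#' `log2(normalized + pseudocount)` values. The per-site pooled variance is
#' shrunk halfway toward the global mean variance (a plug-in estimated from
#' all sites), and the moderated t statistic is referred to a t
#' distribution with Welch-Satterthwaite effective degrees of freedom: for
#' the equal-weight combination of a chi-squared variance estimate with an
#' (effectively deterministic) global constant this is four times the
#' residual degrees of freedom. Benjamini-Hochberg q-values
#' are computed over all sites, and sites are labeled with the default
#' thresholds of [classify_specificity()].
#'
#' @param m a [signal_matrix()]; raw matrices are depth-normalized first.
#' @param group_a,group_b sample_ids of the two groups (>= 2 replicates each).
#' @param pseudocount added before log2 (default 1).
#' @return data frame of class `diff_results`: site_id, log2fc (A over B),
#'   stat, pvalue, qvalue, label.
#' @export
differential_test <- function(m, group_a, group_b, pseudocount = 1) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs >= 2 replicates for a variance estimate")
  assert_that(all(c(group_a, group_b) %in% m$samples$sample_id),
              "unknown sample ids in groups")
  m <- ensure_normalized(m)
  x <- log2(m$values + pseudocount)
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  df_resid <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df_resid
  s2_mod <- 0.5 * s2 + 0.5 * mean(s2)
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  log2fc <- ma - mb
  stat <- ifelse(se > 0, log2fc / se, 0)
  # Satterthwaite: var(0.5 s^2 + 0.5 s0^2) = 0.25 var(s^2) => 4x residual df
  df_total <- 4 * df_resid
  pvalue <- 2 * stats::pt(-abs(stat), df = df_total)
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  qvalue <- stats::p.adjust(pvalue, method = "BH")
  res <- data.frame(site_id = rownames(m$values), log2fc = log2fc,
                    stat = stat, pvalue = pvalue, qvalue = qvalue,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res <- classify_specificity(res)
  class(res) <- c("diff_results", "data.frame")
  res
}

#' Label sites by cell-type specificity
#'
#' `A_specific` iff `qvalue < q_threshold` and `log2fc >= lfc_threshold`;
#' `B_specific` symmetric (boundary inclusive on |log2fc|); everything else
#' `common`. Thresholds are recorded as attributes.
#'
#' @param results output of [differential_test()] (any data frame with
#'   log2fc and qvalue columns).
#' @param q_threshold q-value cutoff (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @return `results` with a `label` column.
#' @export
classify_specificity <- function(results, q_threshold = 0.05, lfc_threshold = 1.0) {
  label <- rep("common", nrow(results))
  sig <- results$qvalue < q_threshold
  label[sig & results$log2fc >= lfc_threshold] <- "A_specific"
  label[sig & results$log2fc <= -lfc_threshold] <- "B_specific"
  results$label <- label
  attr(results, "q_threshold") <- q_threshold
  attr(results, "lfc_threshold") <- lfc_threshold
  results
}

#' Select the most changed sites
#'
#' Returns the `ceil(top_fraction * n)` sites with the most negative
#' (`decreased`) or most positive (`increased`) log2 fold change; ties are
#' broken by smaller p-value, then site_id.
#'
#' @param results a `diff_results` data frame.
#' @param direction `"decreased"` or `"increased"`.
#' @param top_fraction fraction in (0, 1] (default 0.20).
#' @return character vector of site_ids.
#' @export
rank_by_change <- function(results, direction = c("decreased", "increased"),
                           top_fraction = 0.20) {
  direction <- match.arg(direction)
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "top_fraction must be in (0, 1]")
  k <- ceiling(top_fraction * nrow(results))
  key <- if (direction == "decreased") results$log2fc else -results$log2fc
  ord <- order(key, results$pvalue, results$site_id)
  results$site_id[ord[seq_len(k)]]
}

#' PCA of a binding matrix
#'
#' Principal component analysis of `log2(normalized + 1)` signal with sites
#' as features and samples as observations, mean-centered per site. The
#' sign of each component is fixed so the first sample's coordinate is
#' nonnegative, making coordinates reproducible.
#'
#' @param m a [signal_matrix()] with >= 3 samples.
#' @return object of class `pca_result`: list with `coordinates`
#'   (samples x components) and `variance_fraction`.
#' @export
binding_pca <- function(m) {
  assert_that(ncol(m$values) >= 3, "PCA needs at least 3 samples")
  m <- ensure_normalized(m)
  x <- t(log2(m$values + 1))
  if (sum(apply(x, 2, stats::var)) <= .Machine$double.eps) {
    stopf("constant matrix: zero variance, PCA undefined")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pc$x
  flip <- coords[1, ] < 0
  coords[, flip] <- -coords[, flip]
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = coords, variance_fraction = vf),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("binding PCA\n")
  vf <- x$variance_fraction
  for (i in seq_len(min(3, length(vf)))) {
    cat(sprintf("  PC-%d: %.1f%% of variance\n", i, 100 * vf[i]))
  }
  invisible(x)
}

#' Write a differential results table
#' @param results a `diff_results` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
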