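#' Deconvolve common sites into lineage versus housekeeping
#'
#' A common site is a `lineage` site iff its epithelial accessibility
#' exceeds that of *each* of the other three lineages (endothelial, immune,
#' mesenchymal) by at least `lfc_threshold` on the log2 scale (with
#' pseudocount); otherwise it is `housekeeping`. The ALL-lineages
#' quantifier is the strict reading of "higher accessibility in the
#' epithelial lineage" and makes the rule deterministic.
#'
#' @param common_sites site_ids to classify.
#' @param acc lineage accessibility table: data frame with columns
#'   `site_id`, `epithelial`, `endothelial`, `immune`, `mesenchymal`
#'   (optionally `airway`), nonnegative normalized accessibility.
#' @param lfc_threshold log2 ratio threshold (default 1).
#' @param pseudocount added to both sides of each ratio (default 1).
#' @return data frame: site_id, common_subclass in {lineage, housekeeping}.
#' @export
deconvolve_common <- function(common_sites, acc, lfc_threshold = 1.0,
                              pseudocount = 1) {
  needed <- c("site_id", "epithelial", "endothelial", "immune", "mesenchymal")
  missing_cols <- setdiff(needed, names(acc))
  assert_that(length(missing_cols) == 0,
              "accessibility table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  idx <- match(common_sites, acc$site_id)
  assert_that(!anyNA(idx), "accessibility values missing for some common sites")
  a <- acc[idx, , drop = FALSE]
  lfc_vs <- function(other) log2((a$epithelial + pseudocount) / (other + pseudocount))
  is_lineage <- lfc_vs(a$endothelial) >= lfc_threshold &
    lfc_vs(a$immune) >= lfc_threshold &
    lfc_vs(a$mesenchymal) >= lfc_threshold
  data.frame(site_id = common_sites,
             common_subclass = ifelse(is_lineage, "lineage", "housekeeping"),
             stringsAsFactors = FALSE)
}

#' Lineage sites with low airway accessibility
#'
#' Among lineage sites, returns those whose alveolar-epithelial
#' accessibility exceeds the airway accessibility by at least
#' `lfc_threshold` on the log2 scale, i.e. sites closed in airway cells.
#'
#' @inheritParams deconvolve_common
#' @param lineage_sites site_ids previously classified as lineage.
#' @return character vector of airway-low site_ids.
#' @export
airway_low_subset <- function(lineage_sites, acc, lfc_threshold = 1.0,
                              pseudocount = 1) {
  assert_that("airway" %in% names(acc),
              "accessibility table lacks the airway column")
  idx <- match(lineage_sites, acc$site_id)
  assert_that(!anyNA(idx), "accessibility values missing for some lineage sites")
  a <- acc[idx, , drop = FALSE]
  lfc <- log2((a$epithelial + pseudocount) / (a$airway + pseudocount))
  lineage_sites[lfc >= lfc_threshold]
}

#' Flag progenitor-specific sites
#'
#' Among sites called common between the two mature cell types, flags those
#' whose progenitor signal exceeds the larger of the two mature-cell
#' signals by at least `lfc_threshold` on the log2 scale: binding present
#' in progenitors but lost in both fates.
#'
#' @param m a [signal_matrix()] (raw matrices are depth-normalized).
#' @param progenitor_samples,mature_a_samples,mature_b_samples sample_ids.
#' @param sites site_ids to test (typically the common set).
#' @param lfc_threshold log2 ratio threshold (default 1).
#' @param pseudocount pseudocount (default 1).
#' @return character vector of progenitor-specific site_ids.
#' @export
progenitor_specific_sites <- function(m, progenitor_samples, mature_a_samples,
                                      mature_b_samples, sites = NULL,
                                      lfc_threshold = 1.0, pseudocount = 1) {
  m <- ensure_normalized(m)
  v <- m$values
  sites <- sites %||% rownames(v)
  v <- v[sites, , drop = FALSE]
  prog <- rowMeans(v[, progenitor_samples, drop = FALSE])
  mat <- pmax(rowMeans(v[, mature_a_samples, drop = FALSE]),
              rowMeans(v[, mature_b_samples, drop = FALSE]))
  lfc <- log2((prog + pseudocount) / (mat + pseudocount))
  sites[lfc >= lfc_threshold]
}

#' Classify acquired versus retained binding kinetics
#'
#' Within one cell-type-specific site set, sites are ranked by the log2
#' fold change of mature over progenitor signal. The extreme `fraction`
#' with the largest mature gain are `acquired` (little progenitor binding,
#' gained during differentiation); the extreme `fraction` with the least
#' change are `retained` (already bound in progenitors); the middle is
#' `intermediate`. With `fraction = 0.5` the split is an exhaustive
#' bipartition. Ties are broken by site_id.
#'
#' @param mature_diff a `diff_results`-style data frame from comparing
#'   mature against progenitor samples, with `log2fc` meaning mature over
#'   progenitor.
#' @param fraction window fraction in (0, 0.5] (default 0.20, the
#'   conventional top/bottom window).
#' @param progenitor_signal optional per-site progenitor signal (named
#'   numeric); when supplied, the Spearman agreement between the fold-change
#'   ranking and the progenitor-presence ranking is recorded as the
#'   `ranking_agreement` attribute.
#' @return data frame: site_id, kinetics in {acquired, retained,
#'   intermediate}, ordered as the input.
#' @export
kinetic_classes <- function(mature_diff, fraction = 0.20,
                            progenitor_signal = NULL) {
  assert_that(fraction > 0 && fraction <= 0.5,
              "fraction must be in (0, 0.5]: larger windows would overlap")
  n <- nrow(mature_diff)
  k <- ceiling(fraction * n)
  k_ret <- min(k, n - k)  # at fraction 0.5 with odd n the windows meet
  ord <- order(-mature_diff$log2fc, mature_diff$site_id)
  kinetics <- rep("intermediate", n)
  kinetics[ord[seq_len(k)]] <- "acquired"
  if (k_ret > 0) kinetics[ord[seq.int(n - k_ret + 1L, n)]] <- "retained"
  out <- data.frame(site_id = mature_diff$site_id, kinetics = kinetics,
                    stringsAsFactors = FALSE)
  if (!is.null(progenitor_signal)) {
    ps <- progenitor_signal[mature_diff$site_id]
    attr(out, "ranking_agreement") <-
      stats::cor(rank(-ps), rank(mature_diff$log2fc), method = "spearman")
  }
  out
}

#' Mean binding kinetics per class and timepoint
#'
#' Averages normalized signal per kinetic class across sites and
#' replicates, per condition and timepoint, and reports the log2 fold
#' change of each timepoint against the first. A monotonicity diagnostic
#' (is the class mean nondecreasing/nonincreasing over time) is included.
#'
#' @param m a [signal_matrix()].
#' @param classes data frame with site_id and kinetics columns
#'   (from [kinetic_classes()]).
#' @param timepoints ordered character vector of timepoint labels; must
#'   contain at least 2 levels present in the sample sheet.
#' @param pseudocount pseudocount for the fold changes (default 1).
#' @return data frame: kinetics, condition, timepoint, mean_signal,
#'   log2fc_vs_first, n_sites; plus a `monotonic` attribute.
#' @export
kinetic_profiles <- function(m, classes, timepoints, pseudocount = 1) {
  assert_that(length(timepoints) >= 2, "need >= 2 timepoints")
  m <- ensure_normalized(m)
  rows <- list()
  for (cls in unique(classes$kinetics)) {
    sites <- classes$site_id[classes$kinetics == cls]
    sub <- m$values[sites, , drop = FALSE]
    for (cond in unique(m$samples$condition)) {
      means <- vapply(timepoints, function(tp) {
        cols <- m$samples$sample_id[m$samples$condition == cond &
                                      m$samples$timepoint == tp]
        if (!length(cols)) return(NA_real_)
        mean(sub[, cols, drop = FALSE])
      }, numeric(1))
      present <- !is.na(means)
      if (!any(present)) next
      first <- means[which(present)[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        kinetics = cls, condition = cond, timepoint = timepoints,
        mean_signal = means,
        log2fc_vs_first = log2((means + pseudocount) / (first + pseudocount)),
        n_sites = length(sites), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mono <- vapply(split(out, paste(out$kinetics, out$condition)), function(d) {
    v <- d$mean_signal[!is.na(d$mean_signal)]
    all(diff(v) >= 0) || all(diff(v) <= 0)
  }, logical(1))
  attr(out, "monotonic") <- mono
  out
}

#' Cross-reference accessibility gains with opposite-fate binding
#'
#' Labels each site that gained accessibility in a mutant by overlap
#' (>= 1 bp) with the opposing fate's binding peak set (`opposite_bound`,
#' checked first), the mutant's own fate (`same_bound`), or neither
#' (`unbound`), and reports the three fractions.
#'
#' @param increased_sites [peak_set()] of accessibility gains in the mutant.
#' @param binding_own [peak_set()] of the mutant's own fate's binding sites.
#' @param binding_opposite [peak_set()] of the opposing fate's binding sites.
#' @return list with `labels` (data frame site_id, label) and `fractions`
#'   (named numeric over the three labels).
#' @export
opposite_fate_gain <- function(increased_sites, binding_own, binding_opposite) {
  g <- as_granges(increased_sites)
  opp <- if (nrow(binding_opposite)) {
    GenomicRanges::countOverlaps(g, as_granges(binding_opposite)) > 0
  } else rep(FALSE, nrow(increased_sites))
  own <- if (nrow(binding_own)) {
    GenomicRanges::countOverlaps(g, as_granges(binding_own)) > 0
  } else rep(FALSE, nrow(increased_sites))
  label <- ifelse(opp, "opposite_bound", ifelse(own, "same_bound", "unbound"))
  fr <- c(opposite_bound = mean(label == "opposite_bound"),
          same_bound = mean(label == "same_bound"),
          unbound = mean(label == "unbound"))
  list(labels = data.frame(site_id = increased_sites$site_id, label = label,
                           stringsAsFactors = FALSE),
       fractions = fr)
}

#' Assemble a full site taxonomy table
#'
#' Combines specificity labels, common-site deconvolution,
#' progenitor-specific flags, kinetics and promoter/distal annotation into
#' one table, the package's central output.
#'
#' @param specificity data frame site_id, label (from
#'   [classify_specificity()]).
#' @param subclasses optional data frame site_id, common_subclass.
#' @param progenitor_ids optional site_ids to relabel progenitor_specific.
#' @param kinetics optional data frame site_id, kinetics.
#' @param annotation optional [nearest_tss()] output for locale.
#' @return data frame of class `site_taxonomy`: site_id, specificity,
#'   common_subclass, kinetics, locale.
#' @export
site_taxonomy <- function(specificity, subclasses = NULL,
                          progenitor_ids = NULL, kinetics = NULL,
                          annotation = NULL) {
  out <- data.frame(site_id = specificity$site_id,
                    specificity = specificity$label,
                    common_subclass = "none",
                    kinetics = "not_applicable",
                    locale = "unannotated", stringsAsFactors = FALSE)
  if (!is.null(progenitor_ids)) {
    out$specificity[out$site_id %in% progenitor_ids &
                      out$specificity == "common"] <- "progenitor_specific"
  }
  if (!is.null(subclasses)) {
    idx <- match(out$site_id, subclasses$site_id)
    hit <- !is.na(idx) & out$specificity == "common"
    out$common_subclass[hit] <- subclasses$common_subclass[idx[hit]]
  }
  if (!is.null(kinetics)) {
    idx <- match(out$site_id, kinetics$site_id)
    hit <- !is.na(idx) & out$specificity %in% c("A_specific", "B_specific")
    out$kinetics[hit] <- kinetics$kinetics[idx[hit]]
  }
  if (!is.null(annotation)) {
    idx <- match(out$site_id, annotation$site_id)
    out$locale[!is.na(idx)] <- annotation$locale[idx[!is.na(idx)]]
  }
  class(out) <- c("site_taxonomy", "data.frame")
  out
}

#' @export
print.site_taxonomy <- function(x, ...) {
  cat(sprintf("site_taxonomy: %d sites\n", nrow(x)))
  print(table(specificity = x$specificity))
  common <- x$common_subclass[x$common_subclass != "none"]
  if (length(common)) print(table(common_subclass = common))
  invisible(x)
}
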