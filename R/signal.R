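#' Construct a sample metadata sheet
#'
#' @param sample_id unique sample identifiers.
#' @param condition condition label (cell type, genotype, ...).
#' @param timepoint ordered timepoint label.
#' @param replicate integer replicate index, `>= 1`.
#' @param depth post-filtering library read depth, `> 0`.
#' @param frip optional fraction of reads in peaks, in `[0, 1]`.
#' @return data frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, timepoint, replicate, depth,
                         frip = NULL) {
  n <- length(sample_id)
  frip <- frip %||% rep(NA_real_, n)
  assert_that(!anyDuplicated(sample_id), "sample_ids must be unique")
  assert_that(all(depth > 0), "depth must be > 0")
  assert_that(all(replicate >= 1), "replicate must be >= 1")
  assert_that(all(is.na(frip) | (frip >= 0 & frip <= 1)), "frip must be in [0, 1]")
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = as.character(condition),
                   timepoint = as.character(timepoint),
                   replicate = as.integer(replicate),
                   depth = as.numeric(depth),
                   frip = as.numeric(frip), stringsAsFactors = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a sites-by-samples signal matrix
#'
#' The quantitative substrate of all differential analyses: nonnegative
#' signal (read counts or scaled coverage) for each site and sample, with
#' per-sample metadata attached.
#'
#' @param values numeric matrix, sites x samples, no missing entries,
#'   all `>= 0`. Row names are site_ids, column names sample_ids.
#' @param samples a [sample_sheet()] whose sample_ids match `colnames(values)`.
#' @return object of class `signal_matrix`: list with `values` and `samples`.
#' @export
signal_matrix <- function(values, samples) {
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(!anyNA(values), "values must have no missing entries")
  assert_that(all(values >= 0), "values must be nonnegative")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry site_id rownames and sample_id colnames")
  assert_that(identical(colnames(values), samples$sample_id),
              "colnames(values) must equal samples$sample_id in order")
  structure(list(values = values, samples = samples),
            class = "signal_matrix", normalization = NULL)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d sites x %d samples (normalization: %s)\n",
              nrow(x$values), ncol(x$values),
              attr(x, "normalization") %||% "none"))
  invisible(x)
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param reads_in_peaks count of reads falling in the peak universe.
#' @param total_reads total post-filtering reads; must be `> 0`.
#' @return `reads_in_peaks / total_reads`.
#' @examples
#' compute_frip(8e6, 1e7) # 0.8
#' @export
compute_frip <- function(reads_in_peaks, total_reads) {
  assert_that(all(total_reads > 0), "total_reads must be > 0")
  assert_that(all(reads_in_peaks >= 0 & reads_in_peaks <= total_reads),
              "reads_in_peaks must lie in [0, total_reads]")
  reads_in_peaks / total_reads
}

#' Foreground scale factor (FRiP x depth)
#'
#' The foreground-normalization factor: the FRiP of a sample multiplied by
#' its post-filtering library depth. Dividing a sample's track by this
#' factor (and rescaling by a common constant) makes peak heights directly
#' comparable across samples with different signal-to-background ratios.
#'
#' @param meta one row of a [sample_sheet()] (or the sheet itself, giving a
#'   vector of factors).
#' @return numeric factor(s), `frip * depth`.
#' @export
foreground_scale_factor <- function(meta) {
  assert_that(all(!is.na(meta$frip)),
              "frip is missing; run compute_frip and fill the sample sheet first")
  meta$frip * meta$depth
}

#' Normalize a signal matrix
#'
#' `depth` mode divides each column by its library depth and rescales to
#' counts-per-million. `foreground` mode divides each column by its
#' FRiP x depth factor and rescales by the geometric mean of the FRiP
#' values times one million, which keeps the output on the
#' counts-per-million scale while remaining exactly invariant to a common
#' rescaling of raw values and depths. The result is tagged so it cannot
#' be normalized twice.
#'
#' @param m a [signal_matrix()].
#' @param mode `"depth"` or `"foreground"`.
#' @return a normalized `signal_matrix` with a `normalization` attribute.
#' @export
normalize_matrix <- function(m, mode = c("depth", "foreground")) {
  mode <- match.arg(mode)
  tag <- attr(m, "normalization")
  if (!is.null(tag)) stopf("matrix is already %s-normalized", tag)
  if (mode == "depth") {
    factors <- m$samples$depth / 1e6
  } else {
    factors <- foreground_scale_factor(m$samples)
    assert_that(all(factors > 0), "foreground factors must be > 0 (zero FRiP)")
    factors <- factors / (geometric_mean(m$samples$frip) * 1e6)
  }
  out <- m
  out$values <- sweep(m$values, 2, factors, "/")
  attr(out, "normalization") <- mode
  out
}

# Depth-normalize unless already normalized; used by downstream stages that
# accept raw or normalized input.
ensure_normalized <- function(m) {
  if (is.null(attr(m, "normalization"))) normalize_matrix(m, "depth") else m
}

#' Read / write signal matrices and sample sheets
#'
#' Signal matrices are tab-delimited with a `site_id` first column and one
#' column per sample; sample sheets are tab-delimited with a header.
#'
#' @param path file path.
#' @param samples a [sample_sheet()] for `read_signal_matrix`.
#' @return a [signal_matrix()] or [sample_sheet()].
#' @export
read_signal_matrix <- function(path, samples) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  signal_matrix(vals[, samples$sample_id, drop = FALSE], samples)
}

#' @rdname read_signal_matrix
#' @param m a [signal_matrix()] to write.
#' @export
write_signal_matrix <- function(m, path) {
  df <- data.frame(site_id = rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_signal_matrix
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$condition, df$timepoint, df$replicate,
               df$depth, df$frip)
}

#' @rdname read_signal_matrix
#' @param sheet a [sample_sheet()] to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
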