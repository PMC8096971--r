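#' Assemble a pipeline configuration
#'
#' Paths to the inputs the pipeline consumes plus the thresholds of every
#' stage. Stages whose inputs are absent (`NULL`) are skipped; stages can
#' also be disabled explicitly via `stages`.
#'
#' @param counts path to the sites x samples count table.
#' @param samples path to the sample sheet.
#' @param peaks path to the site peak set (narrowPeak).
#' @param accessibility optional path to the four-lineage accessibility
#'   table (enables lineage/housekeeping deconvolution).
#' @param genome,genes optional paths to the genome FASTA and gene table
#'   (enable locale annotation and motif scanning).
#' @param expression,cells optional paths to the expression matrix and
#'   cell metadata (enable module scoring).
#' @param gains optional path to a BED of mutant accessibility gains
#'   (enables opposite-fate cross-referencing).
#' @param out_dir output directory.
#' @param seed integer seed for the seeded stages (module-score controls).
#' @param q_threshold,lfc_threshold specificity thresholds.
#' @param fraction acquired/retained window fraction, in (0, 0.5].
#' @param distal_bp promoter/distal boundary in bp.
#' @param stages character vector of stages to run, a subset of
#'   `c("differential", "classify", "kinetics", "motif", "module_score",
#'   "crossref")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, peaks, accessibility = NULL,
                            genome = NULL, genes = NULL, expression = NULL,
                            cells = NULL, gains = NULL,
                            out_dir = tempfile("bindfate_run_"), seed = 1,
                            q_threshold = 0.05, lfc_threshold = 1.0,
                            fraction = 0.20, distal_bp = 2000,
                            stages = c("differential", "classify", "kinetics",
                                       "motif", "module_score", "crossref")) {
  cfg <- list(counts = counts, samples = samples, peaks = peaks,
              accessibility = accessibility, genome = genome, genes = genes,
              expression = expression, cells = cells, gains = gains,
              out_dir = out_dir, seed = as.integer(seed),
              q_threshold = q_threshold, lfc_threshold = lfc_threshold,
              fraction = fraction, distal_bp = distal_bp, stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced file exists and every threshold is inside
#' its documented range, without mutating any state.
#'
#' @param cfg a [pipeline_config()].
#' @return character vector of problems; empty when the configuration is
#'   runnable.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  for (f in c("counts", "samples", "peaks")) {
    if (is.null(cfg[[f]])) problems <- c(problems, sprintf("missing required input: %s", f))
  }
  for (f in c("counts", "samples", "peaks", "accessibility", "genome",
              "genes", "expression", "cells", "gains")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("%s file does not exist: %s", f, p))
    }
  }
  if (!is.null(cfg$expression) && is.null(cfg$cells)) {
    problems <- c(problems, "expression given without cell metadata")
  }
  if (cfg$q_threshold <= 0 || cfg$q_threshold >= 1) {
    problems <- c(problems, "q_threshold must be in (0, 1)")
  }
  if (cfg$lfc_threshold < 0) problems <- c(problems, "lfc_threshold must be >= 0")
  if (cfg$fraction <= 0 || cfg$fraction > 0.5) {
    problems <- c(problems, "fraction must be in (0, 0.5]")
  }
  if (cfg$distal_bp <= 0) problems <- c(problems, "distal_bp must be > 0")
  bad <- setdiff(cfg$stages, c("differential", "classify", "kinetics",
                               "motif", "module_score", "crossref"))
  if (length(bad)) problems <- c(problems, sprintf("unknown stage(s): %s",
                                                   paste(bad, collapse = ", ")))
  problems
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: read inputs, depth-normalize,
#' differential binding between the two cell types at the final timepoint,
#' specificity classification plus lineage/housekeeping deconvolution and
#' locale annotation, acquired/retained kinetics against the progenitor
#' timepoint, motif scanning with co-occurrence and spacing statistics,
#' nearest-gene module scores along pseudotime, and opposite-fate
#' cross-referencing of accessibility gains. Outputs and a Markdown report
#' are written under `cfg$out_dir`; a run with the same configuration and
#' seed reproduces identical output checksums.
#'
#' The sample sheet must use conditions `progenitor`, `cellA`, `cellB`;
#' timepoints are taken in order of first appearance.
#'
#' @param cfg a [pipeline_config()].
#' @return a `run_report` list: per-stage parameters, taxonomy counts,
#'   statistic tables and output md5 checksums.
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    stopf("invalid configuration:\n%s", paste("-", problems, collapse = "\n"))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, stages = list())
  outp <- function(name) file.path(cfg$out_dir, name)

  log_stage("io", "reading inputs")
  sheet <- read_sample_sheet(cfg$samples)
  m <- read_signal_matrix(cfg$counts, sheet)
  peaks <- read_peaks(cfg$peaks, "narrowPeak")
  timepoints <- unique(sheet$timepoint)
  mature_tp <- timepoints[length(timepoints)]
  sample_ids <- function(cond, tp) {
    sheet$sample_id[sheet$condition == cond & sheet$timepoint %in% tp]
  }
  report$stages$io <- list(n_sites = nrow(m$values), n_samples = ncol(m$values),
                           timepoints = timepoints)

  norm <- normalize_matrix(m, "depth")

  annotation <- NULL
  if (!is.null(cfg$genes)) {
    genes <- read_genes(cfg$genes)
    annotation <- nearest_tss(peaks, genes, distal_bp = cfg$distal_bp)
  }

  diff_ab <- NULL
  taxonomy <- NULL
  if ("differential" %in% cfg$stages) {
    log_stage("differential", "cellA vs cellB at timepoint %s", mature_tp)
    diff_ab <- differential_test(norm, sample_ids("cellA", mature_tp),
                                 sample_ids("cellB", mature_tp))
    diff_ab <- classify_specificity(diff_ab, cfg$q_threshold, cfg$lfc_threshold)
    write_diff_results(diff_ab, outp("differential.tsv"))
    report$stages$differential <- list(
      n_A = sum(diff_ab$label == "A_specific"),
      n_B = sum(diff_ab$label == "B_specific"),
      n_common = sum(diff_ab$label == "common"))
  }

  if ("classify" %in% cfg$stages && !is.null(diff_ab)) {
    log_stage("classify", "taxonomy assembly")
    common_ids <- diff_ab$site_id[diff_ab$label == "common"]
    prog_ids <- progenitor_specific_sites(
      norm, sample_ids("progenitor", timepoints[1]),
      sample_ids("cellA", mature_tp), sample_ids("cellB", mature_tp),
      sites = common_ids, lfc_threshold = cfg$lfc_threshold)
    subclasses <- NULL
    if (!is.null(cfg$accessibility)) {
      acc <- utils::read.table(cfg$accessibility, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      subclasses <- deconvolve_common(setdiff(common_ids, prog_ids), acc,
                                      lfc_threshold = cfg$lfc_threshold)
    }
    taxonomy <- site_taxonomy(diff_ab[, c("site_id", "label")] |>
                                stats::setNames(c("site_id", "label")),
                              subclasses = subclasses,
                              progenitor_ids = prog_ids,
                              annotation = annotation)
    report$stages$classify <- list(
      specificity = table(taxonomy$specificity),
      common_subclass = table(taxonomy$common_subclass))
  }

  kinetics_tables <- list()
  if ("kinetics" %in% cfg$stages && !is.null(taxonomy)) {
    log_stage("kinetics", "acquired/retained classification")
    prog_samples <- sample_ids("progenitor", timepoints[1])
    for (fate in c("A", "B")) {
      spec_ids <- taxonomy$site_id[taxonomy$specificity == paste0(fate, "_specific")]
      if (length(spec_ids) < 2) next
      mature_samples <- sample_ids(paste0("cell", fate), mature_tp)
      sub <- norm
      sub$values <- sub$values[spec_ids, , drop = FALSE]
      attr(sub, "normalization") <- attr(norm, "normalization")
      kd <- differential_test(sub, mature_samples, prog_samples)
      kin <- kinetic_classes(kd, fraction = cfg$fraction)
      kinetics_tables[[fate]] <- kin
      idx <- match(kin$site_id, taxonomy$site_id)
      taxonomy$kinetics[idx] <- kin$kinetics
    }
    report$stages$kinetics <- lapply(kinetics_tables,
                                     function(k) table(k$kinetics))
  }
  if (!is.null(taxonomy)) {
    utils::write.table(taxonomy, outp("taxonomy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("motif" %in% cfg$stages && !is.null(cfg$genome) && !is.null(taxonomy)) {
    log_stage("motif", "scanning site sequences")
    genome <- read_genome_fasta(cfg$genome)
    seqs <- site_sequences(genome, peaks)
    motifs <- bundled_motifs()
    hits <- scan_sites(seqs, motifs[c("NKX", "TEAD")])
    utils::write.table(hits, outp("motif_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sets <- list(
      A_specific = taxonomy$site_id[taxonomy$specificity == "A_specific"],
      B_specific = taxonomy$site_id[taxonomy$specificity == "B_specific"],
      common = taxonomy$site_id[taxonomy$specificity %in%
                                  c("common", "progenitor_specific")])
    cooc <- cooccurrence_fraction(sets, hits, "TEAD")
    spacing <- motif_spacing(hits, motifs$TEAD, motifs$NKX)
    utils::write.table(cooc, outp("motif_cooccurrence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$motif <- list(cooccurrence = cooc,
                                spacing_mean = spacing$mean_distance,
                                spacing_n = spacing$n_sites)
  }

  if ("module_score" %in% cfg$stages && !is.null(cfg$expression) &&
      !is.null(annotation) && length(kinetics_tables)) {
    log_stage("module_score", "nearest-gene module scores along pseudotime")
    expr <- read_expression_set(cfg$expression, cfg$cells)
    branches <- unique(expr$cells$branch)
    if (length(branches) == 2) {
      pt <- expr$cells$pseudotime
      b2 <- expr$cells$branch == branches[2]
      expr$cells$pseudotime[b2] <- align_branch_endpoints(pt[!b2], pt[b2])
    }
    trends <- list()
    for (fate in names(kinetics_tables)) {
      kin <- kinetics_tables[[fate]]
      for (kcls in c("acquired", "retained")) {
        ids <- kin$site_id[kin$kinetics == kcls]
        if (!length(ids)) next
        gs <- sites_to_gene_set(ids, annotation)
        track <- compute_module_score(expr, gs, seed = cfg$seed,
                                      gene_set_id = paste0(fate, "_", kcls))
        for (br in unique(expr$cells$branch)) {
          tr <- trend_along_pseudotime(track, branch = br)
          trends[[paste0(fate, "_", kcls, "_", br)]] <-
            list(gene_set = paste0(fate, "_", kcls), branch = br,
                 rho = tr$rho, n_genes = length(gs))
        }
      }
    }
    report$stages$module_score <- trends
  }

  if ("crossref" %in% cfg$stages && !is.null(cfg$gains) && !is.null(taxonomy)) {
    log_stage("crossref", "opposite-fate accessibility gains")
    gains <- read_peaks(cfg$gains, "bed")
    own <- peaks[peaks$site_id %in%
                   taxonomy$site_id[taxonomy$specificity == "A_specific"], ]
    opp <- peaks[peaks$site_id %in%
                   taxonomy$site_id[taxonomy$specificity == "B_specific"], ]
    class(own) <- class(opp) <- c("peak_set", "data.frame")
    xr <- opposite_fate_gain(gains, own, opp)
    utils::write.table(xr$labels, outp("gain_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$crossref <- list(fractions = xr$fractions,
                                   n_gains = nrow(gains))
  }

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  report$checksums <- tools::md5sum(outputs)
  write_run_report(report, outp("report.md"))
  report$checksums <- tools::md5sum(list.files(cfg$out_dir, full.names = TRUE))
  class(report) <- "run_report"
  report
}

#' Read a genome FASTA into named chromosome strings
#'
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

format_report_value <- function(x) {
  if (is.table(x)) paste(names(x), as.vector(x), sep = ": ", collapse = ", ")
  else if (is.numeric(x)) paste(signif(x, 4), collapse = ", ")
  else paste(unlist(x), collapse = ", ")
}

write_run_report <- function(report, path) {
  lines <- c("# bindfate run report", "")
  for (stage in names(report$stages)) {
    lines <- c(lines, paste0("## ", stage), "")
    rec <- report$stages[[stage]]
    for (nm in names(rec)) {
      val <- rec[[nm]]
      if (is.list(val) && !is.null(val$rho)) {
        lines <- c(lines, sprintf("- %s: rho = %.3f (n_genes = %d)",
                                  nm, val$rho, val$n_genes))
      } else {
        lines <- c(lines, sprintf("- %s: %s", nm, format_report_value(val)))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("bindfate run_report; stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
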