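#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: a toy genome
#' carrying one planted binding site plus one designated nearest gene per
#' tile, negative-binomial ChIP signal with the seven-class site taxonomy
#' (cell-type-specific acquired/retained for fates A and B, lineage,
#' housekeeping, progenitor-specific), four-lineage accessibility, planted
#' partner motifs with controlled spacing, and bifurcating-pseudotime
#' expression coupled to the binding classes. All randomness flows from
#' `seed` through per-stage substreams.
#'
#' @param seed top-level integer seed.
#' @param n_sites named counts per site class.
#' @param effect_size log2 separation between bound and unbound signal.
#' @param nb_dispersion negative-binomial dispersion of site counts.
#' @param acc_dispersion negative-binomial dispersion of the pseudo-bulk
#'   accessibility values (lower than the per-library ChIP dispersion since
#'   pseudo-bulk aggregates many cells).
#' @param baseline unbound mean count per site.
#' @param depth nominal per-sample library depth (per-sample depths vary
#'   +/- 30% around this).
#' @param n_replicates replicates per condition/timepoint.
#' @param timepoints ordered labels: embryonic-like progenitor stage,
#'   postnatal-like intermediate, adult-like mature.
#' @param site_width planted site width in bp.
#' @param tile_width genomic tile per site+gene pair in bp.
#' @param distal_offset,proximal_offset TSS offsets from the site center
#'   for distal (> 2 kb) and promoter-proximal sites.
#' @param distal_prob named per-class probability that a site is distal.
#' @param genome optional named chromosome lengths; auto-sized when `NULL`.
#' @param n_cells_per_branch cells per differentiation branch.
#' @param expr_dispersion negative-binomial dispersion of expression.
#' @param n_filler_genes unlinked constant-expression genes emulating the
#'   transcriptome complement.
#' @param n_shutdown_genes progenitor-program genes declining along both
#'   branches at half amplitude (balances the fate programs in
#'   expression-matched control bins).
#' @param n_maturation_genes genes rising along both branches.
#' @param expr_lo,expr_amp ranges for per-gene basal level and amplitude
#'   (normalized-expression scale).
#' @param branch_T named pseudotime endpoints for branches A and B (B ends
#'   earlier so endpoint alignment is exercised).
#' @param airway_low_fraction fraction of lineage sites closed in airway
#'   cells.
#' @param opposite_fraction fraction of mutant accessibility gains placed
#'   on opposite-fate binding sites.
#' @param n_gains number of mutant accessibility-gain sites.
#' @param spacing_mean,spacing_sd NKX-TEAD center spacing distribution in
#'   bp (truncated at 0).
#' @param motif_plan data frame (class, motif_id, prob) of per-class motif
#'   planting probabilities; `NULL` for the default plan.
#' @param perturbation `"none"`, `"partner_loss"` (partner-factor knockout:
#'   merged trajectory, fate-A genes down, fate-B genes up) or `"tf_loss"`
#'   (lineage-factor knockout: opposite-fate gains without upregulation).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             n_sites = c(A_acquired = 600, A_retained = 600,
                                         B_acquired = 600, B_retained = 600,
                                         lineage = 300, housekeeping = 300,
                                         progenitor = 300),
                             effect_size = 3.0, nb_dispersion = 0.1,
                             acc_dispersion = 0.05,
                             baseline = 50, depth = 2e6, n_replicates = 3,
                             timepoints = c("E", "P", "A"),
                             site_width = 500, tile_width = 4200,
                             distal_offset = 2050, proximal_offset = 800,
                             distal_prob = c(A_acquired = 0.9, A_retained = 0.9,
                                             B_acquired = 0.9, B_retained = 0.9,
                                             lineage = 0.9, housekeeping = 0.55,
                                             progenitor = 0.9),
                             genome = NULL,
                             n_cells_per_branch = 300, expr_dispersion = 1.5,
                             n_filler_genes = 20000, n_shutdown_genes = 2400,
                             n_maturation_genes = 300,
                             expr_lo = c(0.02, 0.2), expr_amp = c(0.3, 2.5),
                             branch_T = c(A = 10, B = 8),
                             airway_low_fraction = 0.38,
                             opposite_fraction = 0.10, n_gains = 1500,
                             spacing_mean = 52, spacing_sd = 5,
                             motif_plan = NULL,
                             perturbation = c("none", "partner_loss", "tf_loss")) {
  perturbation <- match.arg(perturbation)
  assert_that(all(n_sites >= 0), "site counts must be >= 0")
  assert_that(nb_dispersion > 0 && expr_dispersion > 0, "dispersion must be > 0")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              effect_size = effect_size, nb_dispersion = nb_dispersion,
              acc_dispersion = acc_dispersion,
              baseline = baseline, depth = depth, n_replicates = n_replicates,
              timepoints = timepoints, site_width = site_width,
              tile_width = tile_width, distal_offset = distal_offset,
              proximal_offset = proximal_offset, distal_prob = distal_prob,
              genome = genome, n_cells_per_branch = n_cells_per_branch,
              expr_dispersion = expr_dispersion,
              n_filler_genes = n_filler_genes,
              n_shutdown_genes = n_shutdown_genes,
              n_maturation_genes = n_maturation_genes,
              expr_lo = expr_lo, expr_amp = expr_amp, branch_T = branch_T,
              airway_low_fraction = airway_low_fraction,
              opposite_fraction = opposite_fraction, n_gains = n_gains,
              spacing_mean = spacing_mean, spacing_sd = spacing_sd,
              motif_plan = motif_plan %||% default_motif_plan(),
              perturbation = perturbation)
  class(cfg) <- "generator_config"
  cfg
}

SITE_CLASSES <- c("A_acquired", "A_retained", "B_acquired", "B_retained",
                  "lineage", "housekeeping", "progenitor")

#' Default per-class motif planting plan
#'
#' The homeodomain (NKX) motif is planted in every bound site class (62% of
#' housekeeping sites); the TEAD motif at 73% of fate-A-specific, 35% of
#' common, and 23% of fate-B-specific sites, with NKX-TEAD spacing drawn
#' from the configured distribution; CEBP marks fate-B sites, CTCF
#' housekeeping sites and FOXA lineage sites.
#'
#' @return data frame with columns class, motif_id, prob.
#' @export
default_motif_plan <- function() {
  rbind(
    data.frame(class = SITE_CLASSES, motif_id = "NKX",
               prob = c(1, 1, 1, 1, 1, 0.62, 1), stringsAsFactors = FALSE),
    data.frame(class = SITE_CLASSES, motif_id = "TEAD",
               prob = c(0.73, 0.73, 0.23, 0.23, 0.35, 0.35, 0.35),
               stringsAsFactors = FALSE),
    data.frame(class = c("B_acquired", "B_retained"), motif_id = "CEBP",
               prob = 0.6, stringsAsFactors = FALSE),
    data.frame(class = "housekeeping", motif_id = "CTCF", prob = 0.6,
               stringsAsFactors = FALSE),
    data.frame(class = "lineage", motif_id = "FOXA", prob = 0.5,
               stringsAsFactors = FALSE))
}

# One tile per site: the site sits 700 bp into its tile and its designated
# gene's TSS lies distal_offset or proximal_offset downstream, far enough
# from neighbouring tiles that the designated gene is always the nearest.
site_layout <- function(cfg) {
  n_total <- sum(cfg$n_sites)
  if (n_total == 0) {
    return(data.frame(site_id = character(), class = character(),
                      chrom = character(), start = integer(), end = integer(),
                      center = integer(), gene_id = character(),
                      tss = integer(), locale = character(),
                      stringsAsFactors = FALSE))
  }
  assert_that(cfg$tile_width > 700 + cfg$distal_offset + 100,
              "tile_width too small for the distal TSS offset")
  glen <- cfg$genome %||% {
    per_chrom <- ceiling(n_total / 2) * cfg$tile_width + cfg$tile_width
    c(chr1 = per_chrom, chr2 = per_chrom)
  }
  capacity <- floor(glen / cfg$tile_width)
  assert_that(sum(capacity) >= n_total,
              "genome too small: %d sites need >= %d bp total (%d available)",
              n_total, n_total * cfg$tile_width, sum(glen))
  with_seed(substream_seed(cfg$seed, "layout"), {
    classes <- sample(rep(names(cfg$n_sites), cfg$n_sites))
    distal <- stats::runif(n_total) < cfg$distal_prob[classes]
    chrom_idx <- rep(seq_along(glen), pmin(capacity, n_total))[seq_len(n_total)]
    tile_in_chrom <- unlist(lapply(unique(chrom_idx), function(i) {
      seq_len(sum(chrom_idx == i))
    }))
    center <- (tile_in_chrom - 1L) * cfg$tile_width + 700L
    tss <- center + ifelse(distal, cfg$distal_offset, cfg$proximal_offset)
    half <- cfg$site_width %/% 2L
    data.frame(site_id = sprintf("site_%05d", seq_len(n_total)),
               class = classes,
               chrom = names(glen)[chrom_idx],
               start = as.integer(center - half),
               end = as.integer(center - half + cfg$site_width),
               center = as.integer(center),
               gene_id = sprintf("gene_%05d", seq_len(n_total)),
               tss = as.integer(tss),
               locale = ifelse(distal, "distal", "promoter_proximal"),
               stringsAsFactors = FALSE)
  })
}

truth_peaks <- function(truth) {
  peak_set(truth$chrom, truth$start, truth$end, site_id = truth$site_id,
           summit = truth$center - truth$start)
}

#' Generate the toy genome and gene table
#'
#' Emits a random-sequence genome sized to the planted site layout, a gene
#' model in which every planted site has a designated nearest gene, and the
#' per-site truth table. Deterministic per seed.
#'
#' @param cfg a [generator_config()].
#' @return list: `genome` (named character chromosome sequences), `genes`
#'   ([gene_model()]), `peaks` ([peak_set()]), `truth` (per-site truth).
#' @export
generate_genome_and_genes <- function(cfg) {
  truth <- site_layout(cfg)
  glen <- cfg$genome %||% {
    n_total <- max(sum(cfg$n_sites), 1)
    per_chrom <- ceiling(n_total / 2) * cfg$tile_width + cfg$tile_width
    c(chr1 = per_chrom, chr2 = per_chrom)
  }
  genome <- with_seed(substream_seed(cfg$seed, "genome"), {
    vapply(glen, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
  genes <- if (nrow(truth)) {
    strand <- with_seed(substream_seed(cfg$seed, "gene_strand"),
                        sample(c("+", "-"), nrow(truth), replace = TRUE))
    gene_model(truth$gene_id, truth$chrom, truth$tss, strand)
  } else gene_model(character(), character(), integer())
  list(genome = genome, genes = genes, peaks = truth_peaks(truth), truth = truth)
}

# Bound-state indicator per class for each (condition, timepoint):
# acquired sites ramp on in the target fate only; retained sites start on
# and ramp off in the alternative fate; lineage/housekeeping stay on;
# progenitor-specific decay in both fates.
bound_indicator <- function(class, condition, timepoint_index) {
  ramp_up <- c(0, 0.5, 1)[timepoint_index]
  ramp_down <- c(1, 0.5, 0)[timepoint_index]
  if (condition == "progenitor") {
    return(switch(class,
                  A_acquired = 0, B_acquired = 0,
                  A_retained = 1, B_retained = 1,
                  lineage = 1, housekeeping = 1, progenitor = 1))
  }
  own <- (condition == "cellA" & startsWith(class, "A_")) |
    (condition == "cellB" & startsWith(class, "B_"))
  switch(class,
         A_acquired = , B_acquired = if (own) ramp_up else 0,
         A_retained = , B_retained = if (own) 1 else ramp_down,
         lineage = 1, housekeeping = 1,
         progenitor = ramp_down)
}

#' Generate the binding signal matrix
#'
#' Samples: `n_replicates` progenitor libraries at the first timepoint and
#' cell-type A and B libraries at the later timepoints. Per-site counts are
#' negative-binomial with mean
#' `baseline * 2^(effect_size * bound_indicator) * depth_factor`.
#'
#' @param cfg a [generator_config()].
#' @return list: `m` (raw-count [signal_matrix()] with depths and FRiP in
#'   the sample sheet), `peaks`, `truth`.
#' @export
generate_binding_signal <- function(cfg) {
  truth <- site_layout(cfg)
  tps <- cfg$timepoints
  grid <- rbind(
    data.frame(condition = "progenitor", timepoint = tps[1],
               stringsAsFactors = FALSE),
    expand.grid(condition = c("cellA", "cellB"), timepoint = tps[-1],
                stringsAsFactors = FALSE))
  grid <- grid[rep(seq_len(nrow(grid)), each = cfg$n_replicates), ]
  grid$replicate <- rep(seq_len(cfg$n_replicates), length.out = nrow(grid))
  grid$sample_id <- sprintf("%s_%s_r%d", grid$condition, grid$timepoint,
                            grid$replicate)
  with_seed(substream_seed(cfg$seed, "binding"), {
    depths <- round(cfg$depth * stats::runif(nrow(grid), 0.7, 1.3))
    tp_index <- match(grid$timepoint, tps)
    ind <- vapply(seq_len(nrow(grid)), function(j) {
      vapply(truth$class, bound_indicator, numeric(1),
             condition = grid$condition[j], timepoint_index = tp_index[j])
    }, numeric(nrow(truth)))
    mu <- cfg$baseline * 2^(cfg$effect_size * ind)
    mu <- sweep(mu, 2, depths / cfg$depth, "*")
    vals <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow(mu), ncol(mu))
    rownames(vals) <- truth$site_id
    colnames(vals) <- grid$sample_id
    sheet <- sample_sheet(grid$sample_id, grid$condition, grid$timepoint,
                          grid$replicate, depths,
                          frip = compute_frip(colSums(vals), depths))
    list(m = signal_matrix(vals, sheet), peaks = truth_peaks(truth),
         truth = truth)
  })
}

#' Generate four-lineage pseudo-bulk accessibility
#'
#' Lineage-restricted site classes are accessible (mean
#' `baseline * 2^effect_size`) in the epithelial lineage only; housekeeping
#' sites are accessible in all four lineages. A planted fraction of lineage
#' sites is additionally closed in airway cells; `airway_low` in the truth
#' records the planted flag.
#'
#' @param cfg a [generator_config()].
#' @param truth per-site truth from [generate_binding_signal()].
#' @return list: `acc` (data frame site_id, epithelial, endothelial,
#'   immune, mesenchymal, airway), `truth` (with `airway_low` column).
#' @export
generate_lineage_accessibility <- function(cfg, truth) {
  with_seed(substream_seed(cfg$seed, "accessibility"), {
    n <- nrow(truth)
    hi <- cfg$baseline * 2^cfg$effect_size
    lo <- cfg$baseline
    draw <- function(mu) stats::rnbinom(n, mu = mu, size = 1 / cfg$acc_dispersion)
    everywhere <- truth$class == "housekeeping"
    epi_mu <- rep(hi, n)
    other_mu <- ifelse(everywhere, hi, lo)
    airway_low <- truth$class == "lineage" &
      stats::runif(n) < cfg$airway_low_fraction
    airway_mu <- ifelse(airway_low, lo, epi_mu)
    acc <- data.frame(site_id = truth$site_id,
                      epithelial = draw(epi_mu),
                      endothelial = draw(other_mu),
                      immune = draw(other_mu),
                      mesenchymal = draw(other_mu),
                      airway = draw(airway_mu), stringsAsFactors = FALSE)
    truth$airway_low <- airway_low
    list(acc = acc, truth = truth)
  })
}

#' Plant motif instances into the genome
#'
#' Writes consensus motif instances into site sequences according to the
#' per-class plan: the NKX motif near the site center, the TEAD motif at a
#' center-to-center distance drawn from the configured spacing
#' distribution, other motifs at random conflict-free offsets. Placements
#' (site-relative offsets, strands) are recorded in the motif truth table.
#'
#' @param cfg a [generator_config()].
#' @param genome named chromosome sequences from
#'   [generate_genome_and_genes()].
#' @param truth per-site truth table.
#' @return list: `genome` (modified), `motif_truth` (data frame site_id,
#'   motif_id, offset, strand).
#' @export
plant_motifs <- function(cfg, genome, truth) {
  motifs <- bundled_motifs()
  plan <- cfg$motif_plan
  assert_that(all(plan$motif_id %in% names(motifs)),
              "motif plan references motifs not bundled: %s",
              paste(setdiff(plan$motif_id, names(motifs)), collapse = ", "))
  width <- cfg$site_width
  peaks <- truth_peaks(truth)
  seqs <- site_sequences(genome, peaks)
  rows <- list()
  with_seed(substream_seed(cfg$seed, "motifs"), {
    planted <- matrix(FALSE, nrow(truth),
                      length(unique(plan$motif_id)),
                      dimnames = list(truth$site_id, unique(plan$motif_id)))
    for (k in seq_len(nrow(plan))) {
      idx <- which(truth$class == plan$class[k])
      hit <- idx[stats::runif(length(idx)) < plan$prob[k]]
      planted[hit, plan$motif_id[k]] <- TRUE
    }
    nkx_len <- motif_length(motifs$NKX)
    for (i in seq_len(nrow(truth))) {
      ids <- colnames(planted)[planted[i, ]]
      if (!length(ids)) next
      sid <- truth$site_id[i]
      s_local <- seqs[[sid]]
      used <- integer(0)  # occupied [start, end) windows within the site
      place <- function(motif, offset) {
        L <- motif_length(motif)
        strand <- sample(c("+", "-"), 1)
        inst <- consensus_seq(motif)
        if (strand == "-") inst <- revcomp(inst)
        substr(s_local, offset + 1L, offset + L) <<- inst
        used <<- c(used, seq.int(offset, offset + L - 1L))
        rows[[length(rows) + 1L]] <<- data.frame(
          site_id = sid, motif_id = motif$motif_id,
          offset = offset, strand = strand, stringsAsFactors = FALSE)
      }
      free_offset <- function(L) {
        for (try in 1:50) {
          o <- sample.int(width - L + 1L, 1) - 1L
          if (!any(seq.int(o, o + L - 1L) %in% used)) return(o)
        }
        NA_integer_
      }
      nkx_center <- NA_integer_
      if ("NKX" %in% ids) {
        off <- width %/% 2L - nkx_len %/% 2L + sample.int(21L, 1) - 11L
        place(motifs$NKX, off)
        nkx_center <- off + nkx_len %/% 2L
      }
      if ("TEAD" %in% ids) {
        L <- motif_length(motifs$TEAD)
        if (!is.na(nkx_center)) {
          d <- max(0, round(stats::rnorm(1, cfg$spacing_mean, cfg$spacing_sd)))
          side <- sample(c(-1L, 1L), 1)
          center <- nkx_center + side * d
          if (center - L %/% 2L < 0 || center - L %/% 2L + L > width) {
            center <- nkx_center - side * d
          }
          off <- center - L %/% 2L
        } else {
          off <- free_offset(L)
        }
        if (!is.na(off) && off >= 0 && off + L <= width &&
            !any(seq.int(off, off + L - 1L) %in% used)) {
          place(motifs$TEAD, off)
        } else {
          off <- free_offset(L)
          if (!is.na(off)) place(motifs$TEAD, off)
        }
      }
      for (id in setdiff(ids, c("NKX", "TEAD"))) {
        off <- free_offset(motif_length(motifs[[id]]))
        if (!is.na(off)) place(motifs[[id]], off)
      }
      seqs[[sid]] <- s_local
    }
  })
  # splice the modified site sequences back, one paste per chromosome
  for (ch in unique(truth$chrom)) {
    idx <- which(truth$chrom == ch)
    idx <- idx[order(truth$start[idx])]
    bounds <- c(0L, as.vector(rbind(truth$start[idx], truth$end[idx])),
                nchar(genome[[ch]]))
    gap_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
    gap_end <- bounds[seq(2, length(bounds), by = 2)]
    gaps <- substring(genome[[ch]], gap_start + 1L, gap_end)
    pieces <- character(2 * length(idx) + 1)
    pieces[seq(1, length(pieces), by = 2)] <- gaps
    pieces[seq(2, length(pieces) - 1, by = 2)] <- seqs[truth$site_id[idx]]
    genome[[ch]] <- paste(pieces, collapse = "")
  }
  motif_truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), motif_id = character(),
               offset = integer(), strand = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, motif_truth = motif_truth)
}

#' Extract site sequences from a genome
#'
#' @param genome named chromosome sequences.
#' @param peaks a [peak_set()].
#' @return named character vector of site sequences.
#' @export
site_sequences <- function(genome, peaks) {
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
  }, "")
  names(out) <- peaks$site_id
  out
}

# Per-gene expression programs along the two branches (or the merged
# perturbation trajectory). Levels are on the normalized single-cell
# scale; `amp` is the program amplitude, `shape` one of the stylized
# trajectories.
expression_programs <- function(cfg, truth) {
  lo <- function(n) stats::runif(n, cfg$expr_lo[1], cfg$expr_lo[2])
  amp <- function(n) exp(stats::runif(n, log(cfg$expr_amp[1]), log(cfg$expr_amp[2])))
  const_level <- function(n) exp(stats::runif(n, log(0.05), log(3)))
  mk <- function(gene_id, shape, n, half = FALSE) {
    if (n == 0) return(NULL)
    a <- amp(n)
    if (half) a <- a / 2
    data.frame(gene_id = gene_id, shape = shape, lo = lo(n), amp = a,
               stringsAsFactors = FALSE)
  }
  shape_of_class <- c(A_acquired = "up_A", A_retained = "up_A",
                      B_acquired = "up_B", B_retained = "up_B",
                      lineage = "const_mid", housekeeping = "const_mid",
                      progenitor = "down_both")
  if (cfg$perturbation == "partner_loss") {
    shape_of_class <- c(A_acquired = "down_shift", A_retained = "down_shift",
                        B_acquired = "up_shift", B_retained = "up_shift",
                        lineage = "const_mid", housekeeping = "const_mid",
                        progenitor = "const_mid")
  } else if (cfg$perturbation == "tf_loss") {
    # opposite-fate (B-linked) genes stay flat despite accessibility gains;
    # own-fate genes decline, balanced by a rising complement
    shape_of_class <- c(A_acquired = "down_shift", A_retained = "down_shift",
                        B_acquired = "const_mid", B_retained = "const_mid",
                        lineage = "const_mid", housekeeping = "const_mid",
                        progenitor = "const_mid")
  }
  linked <- mk(truth$gene_id, shape_of_class[truth$class], nrow(truth))
  extra <- rbind(
    mk(sprintf("matur_%05d", seq_len(cfg$n_maturation_genes)),
       if (cfg$perturbation == "none") "up_both" else "const_mid",
       cfg$n_maturation_genes),
    mk(sprintf("shutdown_%05d", seq_len(cfg$n_shutdown_genes)),
       switch(cfg$perturbation, none = "down_bal",
              partner_loss = "const_mid", tf_loss = "up_shift_bal"),
       cfg$n_shutdown_genes,
       half = cfg$perturbation %in% c("none", "tf_loss")),
    mk(sprintf("filler_%05d", seq_len(cfg$n_filler_genes)), "const_free",
       cfg$n_filler_genes))
  prog <- rbind(linked, extra)
  prog$level <- ifelse(prog$shape == "const_mid", prog$lo + prog$amp / 2,
                       ifelse(prog$shape == "const_free",
                              const_level(nrow(prog)), NA))
  prog
}

# Mean expression of each program gene in each cell given the cell's
# branch and ramp value (pseudotime / branch endpoint).
program_mu <- function(prog, branch, ramp) {
  n_cells <- length(branch)
  mu <- matrix(0, n_cells, nrow(prog))
  on_A <- branch == "A"
  for (j in seq_len(nrow(prog))) {
    lo <- prog$lo[j]; a <- prog$amp[j]
    mu[, j] <- switch(prog$shape[j],
      up_A = lo + ifelse(on_A, ramp, 0) * a,
      up_B = lo + ifelse(on_A, 0, ramp) * a,
      up_both = lo + ramp * a,
      down_both = lo + (1 - ramp) * a,
      down_bal = lo + (1 - ramp) * a,
      up_shift = lo + ramp * a,
      up_shift_bal = lo + ramp * a,
      down_shift = lo + (1 - ramp) * a,
      const_mid = rep(prog$level[j], n_cells),
      const_free = rep(prog$level[j], n_cells))
  }
  colnames(mu) <- prog$gene_id
  mu
}

#' Generate bifurcating-pseudotime expression coupled to binding classes
#'
#' Two branches (fates A and B) emanate from a shared progenitor state.
#' Genes linked to fate-specific sites follow a low-to-high program along
#' the target branch only - acquired and retained alike, producing the
#' binding/expression dissociation in progenitors; progenitor-linked genes
#' decline along both branches. The transcriptome complement includes a
#' large constant filler, a shared maturation program and a half-amplitude
#' progenitor-shutdown program so expression-matched control bins carry no
#' net pseudotime drift. Perturbation modes emit a single merged
#' trajectory.
#'
#' @param cfg a [generator_config()].
#' @param truth per-site truth table (supplies the gene linkage).
#' @return an [expression_set()]; the per-gene program table is attached as
#'   the `programs` attribute.
#' @export
generate_expression <- function(cfg, truth) {
  with_seed(substream_seed(cfg$seed, "expression"), {
    n <- cfg$n_cells_per_branch
    if (cfg$perturbation == "none") {
      branch <- rep(c("A", "B"), each = n)
      endpoint <- cfg$branch_T[branch]
      pt <- stats::runif(2 * n, 0, 1) * endpoint
      ramp <- pt / endpoint
    } else {
      branch <- rep("shift", 2 * n)
      pt <- stats::runif(2 * n, 0, cfg$branch_T[["A"]])
      ramp <- pt / cfg$branch_T[["A"]]
    }
    prog <- expression_programs(cfg, truth)
    mu <- program_mu(prog, branch, ramp)
    vals <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$expr_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
    cell_id <- sprintf("cell_%05d", seq_along(pt))
    rownames(vals) <- cell_id
    cells <- data.frame(cell_id = cell_id, pseudotime = pt, branch = branch,
                        sample = paste0("sim_", branch),
                        stringsAsFactors = FALSE)
    out <- expression_set(vals, cells)
    attr(out, "programs") <- prog
    out
  })
}

#' Generate mutant accessibility gains for opposite-fate cross-referencing
#'
#' Emits accessibility-gain intervals for a fate-A mutant: a planted
#' fraction sits on fate-B (opposite) binding sites, the rest in unbound
#' intergenic space.
#'
#' @param cfg a [generator_config()].
#' @param truth per-site truth table.
#' @return list: `gains` ([peak_set()]), `gain_truth` (data frame site_id,
#'   planted in {opposite_bound, unbound}).
#' @export
generate_gains <- function(cfg, truth) {
  with_seed(substream_seed(cfg$seed, "gains"), {
    n <- cfg$n_gains
    b_sites <- which(truth$class %in% c("B_acquired", "B_retained"))
    opposite <- stats::runif(n) < cfg$opposite_fraction
    n_opp <- sum(opposite)
    pick <- sample(b_sites, n_opp, replace = n_opp > length(b_sites))
    width <- 300L
    chrom <- character(n); start <- integer(n)
    chrom[opposite] <- truth$chrom[pick]
    start[opposite] <- truth$center[pick] - width %/% 2L
    # unbound gains: placed in the far portion of random tiles, clear of
    # both the site (center +/- 250) and the designated TSS
    host <- sample(nrow(truth), n - n_opp, replace = n - n_opp > nrow(truth))
    chrom[!opposite] <- truth$chrom[host]
    start[!opposite] <- truth$center[host] + cfg$distal_offset + 400L +
      sample.int(500L, n - n_opp, replace = TRUE)
    gains <- peak_set(chrom, start, start + width,
                      site_id = sprintf("gain_%05d", seq_len(n)))
    planted <- ifelse(opposite, "opposite_bound", "unbound")
    names(planted) <- sprintf("gain_%05d", seq_len(n))
    list(gains = gains,
         gain_truth = data.frame(site_id = names(planted), planted = planted,
                                 stringsAsFactors = FALSE))
  })
}

#' Two-factor binding matrix with dominant temporal structure
#'
#' Emits a signal matrix whose log-scale means combine a dominant temporal
#' gradient with a weaker cell-type split, the structure expected to put
#' time on PC-1 and cell type on PC-2 of a binding PCA.
#'
#' @param n_sites number of sites.
#' @param n_timepoints timepoints per cell type.
#' @param n_replicates replicates per sample group.
#' @param temporal_sd,celltype_sd log2-scale effect magnitudes of the two
#'   factors (temporal must dominate).
#' @param noise_sd log2-scale residual noise.
#' @param seed integer seed.
#' @return a [signal_matrix()]; sample sheet columns `condition` (cell
#'   type) and `timepoint` carry the factors.
#' @export
simulate_pca_matrix <- function(n_sites = 2000, n_timepoints = 3,
                                n_replicates = 2, temporal_sd = 3,
                                celltype_sd = 1, noise_sd = 0.3, seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = c("cellA", "cellB"),
                        timepoint = seq_len(n_timepoints),
                        stringsAsFactors = FALSE)
    time_z <- scale(grid$timepoint)[, 1]
    ct_z <- ifelse(grid$condition == "cellA", 1, -1)
    u <- stats::rnorm(n_sites)
    v <- stats::rnorm(n_sites)
    log_mu <- 6 + temporal_sd * outer(u, time_z) + celltype_sd * outer(v, ct_z) +
      matrix(stats::rnorm(n_sites * nrow(grid), 0, noise_sd), n_sites)
    vals <- 2^log_mu
    rownames(vals) <- sprintf("site_%05d", seq_len(n_sites))
    colnames(vals) <- sprintf("%s_t%d_r%d", grid$condition, grid$timepoint,
                              grid$replicate)
    sheet <- sample_sheet(colnames(vals), grid$condition,
                          paste0("t", grid$timepoint), grid$replicate,
                          depth = rep(1e6, nrow(grid)))
    signal_matrix(vals, sheet)
  })
}

#' Null two-group count matrix for calibration checks
#'
#' Negative-binomial counts with identical means in both groups, for
#' type-I-error and p-value-uniformity diagnostics of
#' [differential_test()].
#'
#' @param n_sites sites.
#' @param n_per_group replicates per group.
#' @param mu common mean.
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @return a [signal_matrix()] with conditions `groupA`/`groupB`.
#' @export
simulate_null_matrix <- function(n_sites = 2000, n_per_group = 3, mu = 50,
                                 dispersion = 0.1, seed = 1) {
  with_seed(seed, {
    n_samp <- 2 * n_per_group
    vals <- matrix(stats::rnbinom(n_sites * n_samp, mu = mu,
                                  size = 1 / dispersion), n_sites, n_samp)
    rownames(vals) <- sprintf("site_%05d", seq_len(n_sites))
    cond <- rep(c("groupA", "groupB"), each = n_per_group)
    ids <- sprintf("%s_r%d", cond, rep(seq_len(n_per_group), 2))
    colnames(vals) <- ids
    sheet <- sample_sheet(ids, cond, "t1", rep(seq_len(n_per_group), 2),
                          depth = rep(1e6, n_samp))
    signal_matrix(vals, sheet)
  })
}

#' Write a complete synthetic workspace to disk
#'
#' Emits every input the pipeline consumes - genome FASTA, gene table,
#' binding peaks (narrowPeak), signal matrix and sample sheet, lineage
#' accessibility, expression matrix and cell metadata, accessibility
#' gains, truth tables, and an echo of the scalar configuration - all
#' deterministic per seed.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @param include_sequences write the genome FASTA and plant motifs
#'   (default TRUE).
#' @param include_expression write the expression matrix (default TRUE).
#' @return named list of file paths, invisibly.
#' @export
simulate_workspace <- function(cfg, dir, include_sequences = TRUE,
                               include_expression = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- function(name) file.path(dir, name)
  sig <- generate_binding_signal(cfg)
  acc <- generate_lineage_accessibility(cfg, sig$truth)
  truth <- acc$truth
  write_peaks(sig$peaks, p("peaks.narrowPeak"), "narrowPeak")
  write_signal_matrix(sig$m, p("binding_counts.tsv"))
  write_sample_sheet(sig$m$samples, p("samples.tsv"))
  utils::write.table(acc$acc, p("lineage_accessibility.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[c("peaks", "counts", "samples", "accessibility")] <-
    list(p("peaks.narrowPeak"), p("binding_counts.tsv"), p("samples.tsv"),
         p("lineage_accessibility.tsv"))
  if (include_sequences) {
    gg <- generate_genome_and_genes(cfg)
    pm <- plant_motifs(cfg, gg$genome, truth)
    writeLines(unlist(lapply(names(pm$genome), function(ch) {
      c(paste0(">", ch), substring(pm$genome[[ch]],
                                   seq(1, nchar(pm$genome[[ch]]), 70),
                                   pmin(seq(70, nchar(pm$genome[[ch]]) + 69, 70),
                                        nchar(pm$genome[[ch]]))))
    })), p("genome.fa"))
    write_genes(gg$genes, p("genes.tsv"))
    utils::write.table(pm$motif_truth, p("truth_motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[c("genome", "genes", "truth_motifs")] <-
      list(p("genome.fa"), p("genes.tsv"), p("truth_motifs.tsv"))
  } else {
    gg <- list(genes = gene_model(truth$gene_id, truth$chrom, truth$tss))
    write_genes(gg$genes, p("genes.tsv"))
    paths$genes <- p("genes.tsv")
  }
  if (include_expression) {
    expr <- generate_expression(cfg, truth)
    write_expression_set(expr, p("expression.tsv"), p("cells.tsv"))
    paths[c("expression", "cells")] <- list(p("expression.tsv"), p("cells.tsv"))
  }
  gains <- generate_gains(cfg, truth)
  write_peaks(gains$gains, p("gains.bed"), "bed")
  utils::write.table(gains$gain_truth, p("truth_gains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, p("truth_sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) == 1, TRUE)]
  writeLines(paste0(names(scalars), " = ", unlist(scalars)), p("config.txt"))
  paths[c("gains", "truth_gains", "truth_sites", "config")] <-
    list(p("gains.bed"), p("truth_gains.tsv"), p("truth_sites.tsv"),
         p("config.txt"))
  invisible(paths)
}
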