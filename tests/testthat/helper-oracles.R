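# Independent brute-force oracles and shared fixtures.

# Exhaustive all-pairs nearest-TSS: minimal |center - tss| per peak,
# lexicographic gene_id tie-break. Deliberately quadratic.
oracle_nearest_tss <- function(peaks, genes) {
  center <- ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L,
                   peaks$start + peaks$summit)
  out <- data.frame(site_id = peaks$site_id, gene_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- center[i] - g$tss
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    out$gene_id[i] <- g$gene_id[best]
    out$distance[i] <- d[best]
  }
  out
}

# Quadratic interval-overlap check: >= 1 bp on the half-open intervals.
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Per-offset PWM re-scorer, independent of the vectorized scanner.
oracle_scan <- function(seq, motif) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(motif$ppm)
  score_at <- function(chars) {
    s <- 0
    for (j in seq_len(L)) {
      if (!chars[j] %in% c("A", "C", "G", "T")) return(-Inf)
      s <- s + log2(motif$ppm[chars[j], j] / motif$background[match(chars[j], c("A", "C", "G", "T"))])
    }
    s
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (o in 0:(length(bases) - L)) {
    win <- bases[(o + 1):(o + L)]
    s <- score_at(win)
    if (is.finite(s) && s >= motif$score_threshold) {
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "+", score = s)
    }
    rc <- rev(unname(comp[win]))
    rc[is.na(rc)] <- "N"
    s <- score_at(rc)
    if (is.finite(s) && s >= motif$score_threshold) {
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "-", score = s)
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(), strand = character(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Direct binomial upper-tail mass summation.
oracle_binom_upper <- function(k, n, p) {
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

random_peaks <- function(n, seed, chroms = c("chr1", "chr2"), span = 1e5,
                         width_range = c(50, 400)) {
  set.seed(seed)
  start <- sample.int(span, n)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start, start + width,
           site_id = sprintf("p%04d", seq_len(n)))
}

# Shared simulated objects, built once per test run.
sim_cache <- new.env(parent = emptyenv())

default_cfg <- function() generator_config(seed = 20240917)

sim_binding <- function() {
  if (is.null(sim_cache$binding)) sim_cache$binding <- generate_binding_signal(default_cfg())
  sim_cache$binding
}

sim_genome <- function() {
  if (is.null(sim_cache$genome)) {
    cfg <- default_cfg()
    gg <- generate_genome_and_genes(cfg)
    pm <- plant_motifs(cfg, gg$genome, gg$truth)
    sim_cache$genome <- list(cfg = cfg, genes = gg$genes, peaks = gg$peaks,
                             truth = gg$truth, genome = pm$genome,
                             motif_truth = pm$motif_truth)
  }
  sim_cache$genome
}

sim_hits <- function() {
  if (is.null(sim_cache$hits)) {
    sg <- sim_genome()
    seqs <- site_sequences(sg$genome, sg$peaks)
    motifs <- bundled_motifs()
    sim_cache$hits <- scan_sites(seqs, motifs[c("NKX", "TEAD")])
  }
  sim_cache$hits
}

sim_expression <- function() {
  if (is.null(sim_cache$expression)) {
    sim_cache$expression <- generate_expression(default_cfg(), sim_binding()$truth)
  }
  sim_cache$expression
}

group_ids <- function(m, cond, tp) {
  sh <- m$samples
  sh$sample_id[sh$condition == cond & sh$timepoint == tp]
}

truth_specificity <- function(truth) {
  ifelse(grepl("^A_", truth$class), "A_specific",
         ifelse(grepl("^B_", truth$class), "B_specific", "common"))
}
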