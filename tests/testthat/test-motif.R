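toy_motif <- function(id = "TOY", L = 8, seed = 80, threshold = NULL) {
  set.seed(seed)
  ppm <- matrix(0, 4, L)
  for (j in seq_len(L)) {
    w <- runif(4, 0.02, 1)
    ppm[, j] <- w / sum(w)
  }
  motif_model(id, ppm, score_threshold = threshold)
}

test_that("motif models validate their probability matrices", {
  expect_error(motif_model("x", matrix(0.3, 4, 8)), "sum to 1")
  expect_error(motif_model("x", matrix(0.25, 4, 3)), "length")
  m <- toy_motif()
  expect_equal(colSums(m$ppm), rep(1, 8))
  expect_equal(m$score_threshold, 0.8 * m$max_score)
})

test_that("the consensus sequence scores the maximum at offset 0", {
  m <- toy_motif(seed = 81)
  hits <- scan_pwm(consensus_seq(m), m)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 0L)
  expect_equal(fwd$score, m$max_score, tolerance = 1e-12)
})

test_that("N-containing and short sequences yield no hits", {
  m <- toy_motif(seed = 82)
  expect_equal(nrow(scan_pwm(strrep("N", 50), m)), 0)
  expect_equal(nrow(scan_pwm("ACG", m)), 0)
})

test_that("scanning agrees with the per-offset brute-force oracle", {
  for (seed in c(83, 84, 85)) {
    m <- toy_motif(seed = seed, threshold = 2)  # permissive: many hits
    seq <- with_seed(seed * 7, paste(sample(c("A", "C", "G", "T", "N"), 300,
                                            replace = TRUE,
                                            prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                                     collapse = ""))
    got <- scan_pwm(seq, m)
    want <- oracle_scan(seq, m)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors coordinates", {
  m <- toy_motif(seed = 86, threshold = 3)
  seq <- with_seed(87, paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                             collapse = ""))
  # plant one forward and one reverse-complement instance so hits exist
  substr(seq, 21, 20 + motif_length(m)) <- consensus_seq(m)
  rc_inst <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus_seq(m))))
  substr(seq, 121, 120 + motif_length(m)) <- rc_inst
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_pwm(seq, m)
  rev <- scan_pwm(rc, m)
  L <- motif_length(m)
  mirrored <- data.frame(offset = nchar(seq) - L - rev$offset,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(fwd$offset, mirrored$offset)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("the printed worked example reproduces: 60% over 1.7% is ~35.3-fold", {
  expect_equal(enrichment_fold(0.60, 0.017), 35.294, tolerance = 1e-3)
  # consistent with the printed 36-fold given rounding of the two percentages
  expect_lt(abs(enrichment_fold(0.60, 0.017) - 36), 1)
})

test_that("enrichment folds and binomial tails match direct computation", {
  m <- bundled_motifs()$NKX
  cons <- consensus_seq(m)
  pad <- function(s) paste0("ACGTACGTAC", s, "CATGCATGCA")
  target <- setNames(c(rep(pad(cons), 8), rep(strrep("A", 30), 2)),
                     sprintf("t%d", 1:10))
  bg <- setNames(rep(strrep("A", 30), 10), sprintf("b%d", 1:10))
  bg[1:2] <- pad(cons)
  e <- motif_enrichment(target, bg, m)
  expect_equal(e$target_fraction, 0.8)
  expect_equal(e$background_fraction, 0.2)
  expect_equal(e$fold, 4)
  expect_equal(e$pvalue, oracle_binom_upper(8, 10, 0.2), tolerance = 1e-12)
  # identical sets: fold 1
  same <- motif_enrichment(target, target, m)
  expect_equal(same$fold, 1)
  # duplication invariance
  dup <- motif_enrichment(c(target, target), c(bg, bg), m)
  expect_equal(dup$fold, e$fold)
  # zero background: infinite fold, floored p
  none <- motif_enrichment(target[1:8], bg[3:10], m)
  expect_equal(none$fold, Inf)
  expect_equal(none$pvalue, oracle_binom_upper(8, 8, 1 / 16), tolerance = 1e-12)
})

test_that("binomial p-values match exact mass summation on larger n", {
  for (cfg in list(c(30, 100, 0.2), c(5, 800, 0.004), c(700, 1000, 0.7))) {
    expect_equal(stats::pbinom(cfg[1] - 1, cfg[2], cfg[3], lower.tail = FALSE),
                 oracle_binom_upper(cfg[1], cfg[2], cfg[3]), tolerance = 1e-9)
  }
})

test_that("co-occurrence fractions count sites with any hit", {
  hits <- data.frame(site_id = c("s1", "s1", "s2"), motif_id = "TEAD",
                     offset = c(5L, 40L, 9L), strand = "+", score = 10)
  fr <- cooccurrence_fraction(list(all = c("s1", "s2"), half = c("s2", "s3"),
                                   none = "s4"), hits, "TEAD")
  expect_equal(fr$fraction, c(1, 0.5, 0))
  expect_warning(cooccurrence_fraction(list(empty = character()), hits, "TEAD"),
                 "empty")
})

test_that("spacing is the per-site minimal center distance", {
  motifs <- bundled_motifs()
  La <- motif_length(motifs$NKX)
  Lb <- motif_length(motifs$TEAD)
  hits <- rbind(
    data.frame(site_id = "s1", motif_id = "NKX", offset = 100L - La %/% 2L,
               strand = "+", score = 10),
    data.frame(site_id = "s1", motif_id = "TEAD", offset = 152L - Lb %/% 2L,
               strand = "+", score = 10),
    data.frame(site_id = "s2", motif_id = "NKX", offset = 20L, strand = "+", score = 10),
    data.frame(site_id = "s2", motif_id = "TEAD", offset = 20L + La %/% 2L - Lb %/% 2L,
               strand = "-", score = 10),
    data.frame(site_id = "s3", motif_id = "NKX", offset = 5L, strand = "+", score = 10))
  sp <- motif_spacing(hits, motifs$NKX, motifs$TEAD)
  expect_equal(sp$n_sites, 2)
  expect_equal(sp$per_site$distance[sp$per_site$site_id == "s1"], 52L)
  expect_equal(sp$per_site$distance[sp$per_site$site_id == "s2"], 0L)
  expect_equal(sp$mean_distance, 26)
})

test_that("planted co-occurrence and spacing are recovered from the default workspace", {
  sg <- sim_genome()
  hits <- sim_hits()
  truth <- sg$truth
  sets <- list(decreased = truth$site_id[grepl("^A_", truth$class)],
               unaffected = truth$site_id[truth$class %in%
                                            c("lineage", "housekeeping", "progenitor")],
               increased = truth$site_id[grepl("^B_", truth$class)])
  fr <- cooccurrence_fraction(sets, hits, "TEAD")
  expect_lt(abs(fr$fraction[fr$set == "decreased"] - 0.73), 0.03)
  expect_lt(abs(fr$fraction[fr$set == "unaffected"] - 0.35), 0.03)
  expect_lt(abs(fr$fraction[fr$set == "increased"] - 0.23), 0.03)
  motifs <- bundled_motifs()
  sp <- motif_spacing(hits, motifs$TEAD, motifs$NKX)
  expect_lt(abs(sp$mean_distance - 52), 2)
})

test_that("motif tables round-trip through the tabular PPM format", {
  m <- toy_motif(seed = 88)
  f <- withr::local_tempfile(fileext = ".txt")
  write_motifs(list(m), f)
  back <- read_motifs(f)[["TOY"]]
  expect_equal(back$ppm, m$ppm, tolerance = 1e-5, ignore_attr = TRUE)
})
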