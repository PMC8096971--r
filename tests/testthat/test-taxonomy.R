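acc_table <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  df$site_id <- sprintf("s%d", seq_len(nrow(df)))
  df
}

test_that("lineage calls need epithelial excess over every other lineage", {
  acc <- acc_table(c(epithelial = 16, endothelial = 2, immune = 2, mesenchymal = 2),
                   c(epithelial = 5, endothelial = 5, immune = 5, mesenchymal = 5),
                   c(epithelial = 16, endothelial = 2, immune = 16, mesenchymal = 2))
  out <- deconvolve_common(acc$site_id, acc)
  expect_equal(out$common_subclass, c("lineage", "housekeeping", "housekeeping"))
  # partition: every site classified exactly once
  expect_equal(sort(out$site_id), sort(acc$site_id))
  expect_true(all(out$common_subclass %in% c("lineage", "housekeeping")))
  expect_error(deconvolve_common(acc$site_id, acc[, -2]), "endothelial")
})

test_that("airway-low subset uses the epithelial/airway ratio", {
  acc <- acc_table(c(epithelial = 8, endothelial = 0, immune = 0,
                     mesenchymal = 0, airway = 0),
                   c(epithelial = 8, endothelial = 0, immune = 0,
                     mesenchymal = 0, airway = 8))
  expect_equal(airway_low_subset(acc$site_id, acc), "s1")
  expect_error(airway_low_subset(acc$site_id, acc[, setdiff(names(acc), "airway")]),
               "airway")
})

test_that("planted airway-low fraction 0.3 is recovered within 0.05", {
  cfg <- generator_config(seed = 71, airway_low_fraction = 0.3)
  sig <- generate_binding_signal(cfg)
  la <- generate_lineage_accessibility(cfg, sig$truth)
  lineage_ids <- sig$truth$site_id[sig$truth$class == "lineage"]
  got <- length(airway_low_subset(lineage_ids, la$acc)) / length(lineage_ids)
  expect_lt(abs(got - 0.3), 0.05)
})

test_that("kinetic windows split extremes and keep the union size right", {
  d <- data.frame(site_id = sprintf("s%02d", 1:10), log2fc = seq(2, -2, length.out = 10),
                  pvalue = 0.01, qvalue = 0.01)
  k <- kinetic_classes(d, fraction = 0.2)
  expect_equal(sum(k$kinetics == "acquired"), 2)
  expect_equal(sum(k$kinetics == "retained"), 2)
  expect_equal(sum(k$kinetics == "intermediate"), 6)
  expect_equal(k$site_id[k$kinetics == "acquired"], c("s01", "s02"))
  half <- kinetic_classes(d, fraction = 0.5)
  expect_false(any(half$kinetics == "intermediate"))
  odd <- kinetic_classes(d[1:9, ], fraction = 0.5)
  expect_equal(as.vector(table(odd$kinetics)[c("acquired", "retained")]), c(5L, 4L))
  expect_error(kinetic_classes(d, fraction = 0.7), "0.5")
})

test_that("planted acquired/retained labels are recovered and the two rankings agree", {
  sig <- sim_binding()
  m <- normalize_matrix(sig$m, "depth")
  d_ab <- differential_test(m, group_ids(m, "cellA", "A"), group_ids(m, "cellB", "A"))
  spec_ids <- d_ab$site_id[d_ab$label == "A_specific"]
  sub <- m
  sub$values <- sub$values[spec_ids, , drop = FALSE]
  attr(sub, "normalization") <- "depth"
  kd <- differential_test(sub, group_ids(m, "cellA", "A"), group_ids(m, "progenitor", "E"))
  prog_sig <- rowMeans(sub$values[, group_ids(m, "progenitor", "E")])
  kin <- kinetic_classes(kd, fraction = 0.5, progenitor_signal = prog_sig)
  truth <- sig$truth
  want <- ifelse(truth$class[match(kin$site_id, truth$site_id)] == "A_acquired",
                 "acquired", "retained")
  expect_gte(mean(kin$kinetics == want), 0.9)
  # fold-change ranking and progenitor-presence ranking coincide
  expect_gte(attr(kin, "ranking_agreement"), 0.9)
})

test_that("kinetic profiles recover the planted ramp shapes", {
  sig <- sim_binding()
  truth <- sig$truth
  m <- normalize_matrix(sig$m, "depth")
  classes <- data.frame(site_id = truth$site_id,
                        kinetics = ifelse(truth$class == "A_acquired", "acquired",
                                   ifelse(truth$class == "A_retained", "retained", "other")))
  classes <- classes[classes$kinetics != "other", ]
  prof <- kinetic_profiles(m, classes, timepoints = c("E", "P", "A"))
  acqA <- prof[prof$kinetics == "acquired" & prof$condition == "cellA", ]
  acqA <- acqA[!is.na(acqA$mean_signal), ]
  expect_true(all(diff(acqA$mean_signal) > 0))
  retB <- prof[prof$kinetics == "retained" & prof$condition == "cellB", ]
  retB <- retB[!is.na(retB$mean_signal), ]
  expect_true(all(diff(retB$mean_signal) < 0))
  retA <- prof[prof$kinetics == "retained" & prof$condition == "cellA", ]
  lfc <- retA$log2fc_vs_first[!is.na(retA$log2fc_vs_first)]
  expect_true(all(abs(lfc) < 0.5))  # flat in the retaining cell type
  const <- m
  const$values[] <- 7
  attr(const, "normalization") <- "depth"
  pc <- kinetic_profiles(const, classes, timepoints = c("E", "P", "A"))
  expect_true(all(pc$log2fc_vs_first[!is.na(pc$log2fc_vs_first)] == 0))
})

test_that("progenitor-specific sites are flagged among common sites", {
  sig <- sim_binding()
  m <- normalize_matrix(sig$m, "depth")
  truth <- sig$truth
  common_ids <- truth$site_id[truth$class %in% c("lineage", "housekeeping", "progenitor")]
  prog <- progenitor_specific_sites(m, group_ids(m, "progenitor", "E"),
                                    group_ids(m, "cellA", "A"),
                                    group_ids(m, "cellB", "A"), sites = common_ids)
  truth_prog <- truth$site_id[truth$class == "progenitor"]
  expect_gte(mean(prog %in% truth_prog), 0.95)
  expect_gte(mean(truth_prog %in% prog), 0.9)
})

test_that("opposite-fate gains are labeled by overlap priority and recover the planted rate", {
  own <- peak_set("chr1", c(1000L, 3000L), c(1500L, 3500L), site_id = c("o1", "o2"))
  opp <- peak_set("chr1", 3400L, 3900L, site_id = "p1")
  gains <- peak_set("chr1", c(1100L, 3450L, 9000L), c(1200L, 3550L, 9100L),
                    site_id = c("g_same", "g_opp", "g_un"))
  res <- opposite_fate_gain(gains, own, opp)
  expect_equal(res$labels$label[match(c("g_same", "g_opp", "g_un"), res$labels$site_id)],
               c("same_bound", "opposite_bound", "unbound"))
  expect_equal(sum(res$fractions), 1)

  cfg <- generator_config(seed = 72, opposite_fraction = 0.12)
  sig <- generate_binding_signal(cfg)
  truth <- sig$truth
  g <- generate_gains(cfg, truth)
  pk <- sig$peaks
  b_ids <- truth$site_id[grepl("^B_", truth$class)]
  a_ids <- truth$site_id[grepl("^A_", truth$class)]
  xr <- opposite_fate_gain(g$gains, pk[pk$site_id %in% a_ids, ],
                           pk[pk$site_id %in% b_ids, ])
  got <- xr$fractions[["opposite_bound"]]
  ci_half <- 1.96 * sqrt(0.12 * 0.88 / cfg$n_gains)
  expect_lt(abs(got - 0.12), ci_half + 0.01)
})

test_that("taxonomy assembly keeps subclasses for common sites only", {
  spec <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                     label = c("A_specific", "common", "common", "B_specific"))
  sub <- data.frame(site_id = c("s2", "s3"), common_subclass = c("lineage", "housekeeping"))
  kin <- data.frame(site_id = c("s1", "s4"), kinetics = c("acquired", "retained"))
  tax <- site_taxonomy(spec, subclasses = sub, progenitor_ids = "s3", kinetics = kin)
  expect_equal(tax$specificity, c("A_specific", "common", "progenitor_specific", "B_specific"))
  expect_equal(tax$common_subclass, c("none", "lineage", "none", "none"))
  expect_equal(tax$kinetics, c("acquired", "not_applicable", "not_applicable", "retained"))
})
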