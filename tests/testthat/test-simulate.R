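small_cfg <- function(seed = 101, ...) {
  generator_config(seed = seed,
                   n_sites = c(A_acquired = 40, A_retained = 40,
                               B_acquired = 40, B_retained = 40,
                               lineage = 20, housekeeping = 20,
                               progenitor = 20),
                   n_cells_per_branch = 60, n_filler_genes = 500,
                   n_shutdown_genes = 160, n_maturation_genes = 20,
                   n_gains = 100, ...)
}

test_that("every generator output is deterministic per seed", {
  cfg <- small_cfg()
  s1 <- generate_binding_signal(cfg)
  s2 <- generate_binding_signal(cfg)
  expect_identical(s1$m$values, s2$m$values)
  expect_identical(s1$truth, s2$truth)
  g1 <- generate_genome_and_genes(cfg)
  g2 <- generate_genome_and_genes(cfg)
  expect_identical(g1$genome, g2$genome)
  e1 <- generate_expression(cfg, s1$truth)
  e2 <- generate_expression(cfg, s1$truth)
  expect_identical(e1$values, e2$values)
  other <- generate_binding_signal(small_cfg(seed = 102))
  expect_false(identical(other$m$values, s1$m$values))
})

test_that("workspace files are byte-identical across runs of one seed", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_workspace(cfg, d1)
  p2 <- simulate_workspace(cfg, d2)
  expect_setequal(names(p1), names(p2))
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
})

test_that("designated nearest genes are recovered exactly by annotation", {
  gg <- generate_genome_and_genes(small_cfg())
  ann <- nearest_tss(gg$peaks, gg$genes)
  idx <- match(ann$site_id, gg$truth$site_id)
  expect_equal(ann$gene_id, gg$truth$gene_id[idx])
  expect_equal(ann$locale, gg$truth$locale[idx])
})

test_that("a genome too small for the site count is refused", {
  cfg <- small_cfg()
  cfg$genome <- c(chr1 = 1e4, chr2 = 1e4)
  expect_error(generate_binding_signal(cfg), "genome too small")
})

test_that("emitted class means track the programmed means within 2 SEM", {
  sig <- sim_binding()
  cfg <- default_cfg()
  m <- sig$m
  truth <- sig$truth
  adultA <- group_ids(m, "cellA", "A")
  depth_factor <- mean(m$samples$depth[match(adultA, m$samples$sample_id)]) / cfg$depth
  for (cls in c("A_acquired", "lineage", "B_acquired")) {
    rows <- truth$site_id[truth$class == cls]
    vals <- m$values[rows, adultA]
    bound <- cls %in% c("A_acquired", "lineage")
    want <- cfg$baseline * 2^(cfg$effect_size * as.numeric(bound)) * depth_factor
    sem <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - want), 2 * sem + 0.05 * want)
  }
})

test_that("zero effect size makes the classes statistically indistinguishable", {
  cfg <- small_cfg(seed = 103, effect_size = 0)
  sig <- generate_binding_signal(cfg)
  m <- normalize_matrix(sig$m, "depth")
  d <- differential_test(m, group_ids(m, "cellA", "A"), group_ids(m, "cellB", "A"))
  expect_lt(mean(d$label != "common"), 0.05)
})

test_that("recovery accuracy is nondecreasing in effect size", {
  acc <- vapply(c(0.5, 1.5, 3.0), function(es) {
    cfg <- generator_config(seed = 104, effect_size = es,
                            n_sites = c(A_acquired = 150, A_retained = 150,
                                        B_acquired = 150, B_retained = 150,
                                        lineage = 75, housekeeping = 75,
                                        progenitor = 75))
    sig <- generate_binding_signal(cfg)
    m <- normalize_matrix(sig$m, "depth")
    d <- differential_test(m, group_ids(m, "cellA", "A"), group_ids(m, "cellB", "A"))
    mean(d$label == truth_specificity(sig$truth))
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.02))
  expect_gt(acc[3], acc[1])
})

test_that("near-zero dispersion drives specificity recovery to 100%", {
  cfg <- small_cfg(seed = 105, nb_dispersion = 1e-4)
  sig <- generate_binding_signal(cfg)
  m <- normalize_matrix(sig$m, "depth")
  d <- differential_test(m, group_ids(m, "cellA", "A"), group_ids(m, "cellB", "A"))
  expect_equal(mean(d$label == truth_specificity(sig$truth)), 1)
})

test_that("lineage accessibility encodes the planted subclass structure", {
  sig <- sim_binding()
  la <- generate_lineage_accessibility(default_cfg(), sig$truth)
  truth <- la$truth
  hk <- truth$class == "housekeeping"
  # housekeeping: all four lineages drawn from one distribution
  hk_means <- colMeans(la$acc[hk, c("epithelial", "endothelial", "immune",
                                    "mesenchymal")])
  expect_lt(diff(range(hk_means)) / mean(hk_means), 0.1)
  lin <- truth$class == "lineage"
  ratio <- log2((la$acc$epithelial[lin] + 1) / (la$acc$endothelial[lin] + 1))
  expect_lt(abs(mean(ratio) - default_cfg()$effect_size), 0.25)
  dec <- deconvolve_common(truth$site_id[hk | lin], la$acc)
  expect_gte(mean(dec$common_subclass ==
                    truth$class[match(dec$site_id, truth$site_id)]), 0.95)
})

test_that("motif planting follows the plan and scanner recovery is near-perfect", {
  sg <- sim_genome()
  hits <- sim_hits()
  mt <- sg$motif_truth
  planted_nkx <- unique(mt$site_id[mt$motif_id == "NKX"])
  found_nkx <- unique(hits$site_id[hits$motif_id == "NKX"])
  expect_gte(mean(planted_nkx %in% found_nkx), 0.999)
  # plan: NKX planted in 100% of fate-A-specific sites
  a_ids <- sg$truth$site_id[grepl("^A_", sg$truth$class)]
  fr <- cooccurrence_fraction(list(a = a_ids), hits, "NKX")
  expect_equal(fr$fraction, 1)
  # planted placements rediscovered at the planted offsets
  merged <- merge(mt[mt$motif_id == "NKX", ], hits[hits$motif_id == "NKX", ],
                  by = c("site_id", "motif_id", "offset"))
  expect_gte(nrow(merged) / sum(mt$motif_id == "NKX"), 0.99)
})

test_that("perturbation generators produce the planted trajectory couplings", {
  truth <- sim_binding()$truth
  cfgp <- generator_config(seed = 106, perturbation = "partner_loss")
  exprp <- generate_expression(cfgp, truth)
  dec <- compute_module_score(exprp, truth$gene_id[grepl("^A_", truth$class)],
                              seed = 9, gene_set_id = "decreased")
  inc <- compute_module_score(exprp, truth$gene_id[grepl("^B_", truth$class)],
                              seed = 9, gene_set_id = "increased")
  expect_lt(trend_along_pseudotime(dec)$rho, -0.8)
  expect_gt(trend_along_pseudotime(inc)$rho, 0.8)
  cfgt <- generator_config(seed = 107, perturbation = "tf_loss")
  exprt <- generate_expression(cfgt, truth)
  gained <- compute_module_score(exprt, truth$gene_id[grepl("^B_", truth$class)],
                                 seed = 9, gene_set_id = "gained")
  expect_lt(abs(trend_along_pseudotime(gained)$rho), 0.3)
})

test_that("progenitor-bound retained sites still start with low expression", {
  truth <- sim_binding()$truth
  expr <- sim_expression()
  early <- expr$cells$pseudotime < 1
  ret_genes <- truth$gene_id[truth$class == "A_retained"]
  progs <- attr(expr, "programs")
  lo_mean <- mean(progs$lo[progs$gene_id %in% ret_genes])
  expect_lt(mean(expr$values[early, ret_genes]), 3 * (lo_mean + 0.1))
})
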