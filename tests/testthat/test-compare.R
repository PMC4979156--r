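mk_enr <- function(gene_id, mark, condition, epsilon) {
  data.frame(gene_id = gene_id, mark = mark, condition = condition,
             epsilon = epsilon, n_values = 1L, stringsAsFactors = FALSE)
}

test_that("differential enrichment subtracts conditions and applies tau", {
  enr <- rbind(
    mk_enr("G1", "H3K9ac", "normal", 15.49),
    mk_enr("G1", "H3K9ac", "cancer", 7.98),
    mk_enr("G2", "H3K9ac", "normal", 0),
    mk_enr("G2", "H3K9ac", "cancer", 0),
    mk_enr("G3", "H3K9ac", "normal", 5.0),
    mk_enr("G3", "H3K9ac", "cancer", 4.7)
  )
  d <- differential_enrichment(enr, "normal", "cancer")
  expect_equal(d$delta[d$gene_id == "G1"], 7.51)
  expect_equal(d$status[d$gene_id == "G1"], "different")
  expect_equal(d$delta[d$gene_id == "G2"], 0)
  expect_equal(d$status[d$gene_id == "G2"], "same") # both-zero case
  d2 <- differential_enrichment(enr, "normal", "cancer", tau = 0.5)
  expect_equal(d2$status[d2$gene_id == "G3"], "same") # |0.3| <= 0.5

  lonely <- rbind(enr, mk_enr("G1", "H3K4me1", "normal", 2))
  expect_warning(differential_enrichment(lonely, "normal", "cancer"), "H3K4me1")
})

test_that("direction sets follow the normal-minus-cancer convention", {
  enr <- rbind(
    mk_enr(c("G1", "G2", "G3"), "m", "normal", c(10, 2, 5)),
    mk_enr(c("G1", "G2", "G3"), "m", "cancer", c(2.49, 8, 5))
  )
  d <- differential_enrichment(enr, "normal", "cancer")
  expect_equal(enrichment_direction_sets(d, "m", "depleted-in-B"), "G1")
  expect_equal(enrichment_direction_sets(d, "m", "enriched-in-B"), "G2")
  # delta = 0 in neither set
  expect_false("G3" %in% c(enrichment_direction_sets(d, "m", "enriched-in-B"),
                           enrichment_direction_sets(d, "m", "depleted-in-B")))
})

test_that("the paired Wilcoxon test handles degenerate and extreme inputs", {
  eq <- rbind(mk_enr(sprintf("G%d", 1:5), "m", "normal", 1:5),
              mk_enr(sprintf("G%d", 1:5), "m", "cancer", 1:5))
  r <- paired_condition_test(eq, "m", "normal", "cancer")
  expect_equal(r$p, 1)
  expect_equal(r$statistic, 0)

  shifted <- rbind(mk_enr(sprintf("G%d", 1:50), "m", "normal", 1:50),
                   mk_enr(sprintf("G%d", 1:50), "m", "cancer", 1:50 + 10))
  r2 <- paired_condition_test(shifted, "m", "normal", "cancer")
  expect_equal(r2$statistic, 0) # all differences negative: V = 0
  expect_lt(r2$p, 1e-6)

  d <- c(rep(2, 10), rep(-2, 10))
  anti <- rbind(mk_enr(sprintf("G%d", 1:20), "m", "normal", 10 + d),
                mk_enr(sprintf("G%d", 1:20), "m", "cancer", rep(10, 20)))
  r3 <- paired_condition_test(anti, "m", "normal", "cancer")
  # V at its null center n(n+1)/4 for the symmetric configuration
  expect_equal(r3$statistic, 20 * 21 / 4)
})

test_that("group comparison tests match hand-computed rank statistics", {
  same <- list(a = 1:9, b = 1:9)
  expect_gt(group_comparison_test(same, "wilcoxon-unpaired")$p, 0.9)

  far <- list(a = rnorm(50), b = rnorm(50) + 100)
  expect_lt(group_comparison_test(far, "wilcoxon-unpaired")$p, 1e-6)

  kw <- group_comparison_test(list(g1 = 1:3, g2 = 4:6, g3 = 7:9), "kruskal-wallis")
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 7.2 for ranks 1..9 in blocks
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))

  expect_error(group_comparison_test(list(a = 1:3, b = numeric(0))),
               class = "tenet_validation_error")
  expect_error(group_comparison_test(list(a = 1:3)), class = "tenet_validation_error")
})

test_that("contingency tables count categories and recompute proportions", {
  lv <- c(rep("TE-free", 2), rep("Mix", 5), rep("SINE-rich", 3))
  cl <- data.frame(gene_id = sprintf("G%d", 1:10), level12 = lv,
                   stringsAsFactors = FALSE)
  cont <- build_contingency(cl, list(all = cl$gene_id))
  expect_equal(unname(cont$counts["Mix", "all"]), 5L)
  expect_equal(sum(cont$counts[, "all"]), 10L)
  expect_equal(sum(cont$proportions[, "all"]), 1)
  expect_equal(unname(cont$percent["SINE-rich", "all"]), 30)
  expect_error(build_contingency(cl, list(bad = "NOPE")),
               class = "tenet_validation_error")
})

test_that("chi-square homogeneity matches closed forms and is symmetric", {
  counts <- cbind(a = c(10, 20), b = c(20, 10))
  rownames(counts) <- c("x", "y")
  r <- chi2_homogeneity(counts, "a", "b")
  expect_equal(r$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30))
  expect_equal(r$df, 1)

  # proportional columns: statistic 0, p = 1
  prop <- cbind(a = c(5, 10, 15), b = c(10, 20, 30))
  rownames(prop) <- c("x", "y", "z")
  r0 <- chi2_homogeneity(prop, "a", "b")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # symmetry in column order and invariance under joint integer scaling
  set.seed(13)
  m <- cbind(a = rpois(6, 30) + 1, b = rpois(6, 50) + 1)
  rownames(m) <- letters[1:6]
  expect_equal(chi2_homogeneity(m, "a", "b")$statistic,
               chi2_homogeneity(m, "b", "a")$statistic)
  m3 <- m * 3L
  expect_equal(chi2_homogeneity(m3, "a", "b")$statistic,
               3 * chi2_homogeneity(m, "a", "b")$statistic)

  zero <- cbind(a = c(0, 0), b = c(1, 2))
  rownames(zero) <- c("x", "y")
  expect_error(chi2_homogeneity(zero, "a", "b"), class = "tenet_validation_error")
})

test_that("bonferroni thresholds and significance flags are consistent", {
  expect_equal(bonferroni_alpha(8), 6.25e-3)
  expect_equal(bonferroni_alpha(20), 0.0025)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_error(bonferroni_alpha(0), class = "tenet_validation_error")

  counts <- cbind(a = c(40, 10, 10), b = c(10, 40, 10))
  rownames(counts) <- c("x", "y", "z")
  r1 <- chi2_homogeneity(counts, "a", "b", n_tests = 1)
  expect_true(r1$significant)
  huge <- ceiling(0.05 / r1$p) + 1
  r2 <- chi2_homogeneity(counts, "a", "b", n_tests = huge)
  expect_false(r2$significant)
})

test_that("DE gene sets respect the padj cutoff and fold-change sign", {
  de <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4", "G5"),
    log2fc = c(2, -3, 0, 1, -1),
    padj = c(0.05, 0.5, 0.01, NA, 0.09),
    stringsAsFactors = FALSE
  )
  s <- de_gene_sets(de)
  expect_equal(s$up, "G1")
  expect_equal(s$down, "G5")
  expect_true(all(c("G2", "G3", "G4") %in% s$unchanged)) # zero lfc / NA / high padj
})

test_that("a planted over-represented category is detected with high power", {
  alpha <- bonferroni_alpha(1)
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    sim <- simulate_genome(sim_config(seed = 5000 + i))
    enr <- enrichment_matrix(sim$genes,
                             sim$peaks[sim$peaks$mark == "H3K27me3", ])
    d <- differential_enrichment(enr, "normal", "cancer", tau = 1)
    grp <- enrichment_direction_sets(d, "H3K27me3", "enriched-in-B", tau = 1)
    cont <- build_contingency(
      sim$truth$categories,
      list(total_genome = sim$truth$categories$gene_id, shifted = grp)
    )
    p <- chi2_homogeneity(cont, "shifted", "total_genome")$p
    hits <- hits + (p < alpha)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("intersecting DE and direction sets reproduces planted group structure", {
  cfg <- sim_config(seed = 17, de_coupling = 1)
  sim <- simulate_genome(cfg)
  enr <- enrichment_matrix(sim$genes, sim$peaks[sim$peaks$mark == "H3K27me3", ])
  d <- differential_enrichment(enr, "normal", "cancer", tau = 1)
  enriched <- enrichment_direction_sets(d, "H3K27me3", "enriched-in-B", tau = 1)
  down <- de_gene_sets(sim$de)$down
  grp <- intersect(down, enriched)
  tr <- sim$truth$categories
  # with full coupling, every shifted (TE-carrying) gene is down-regulated,
  # so the group is dominated by TE-carrying categories and TE-free vanishes
  expect_gt(length(grp), 50)
  expect_equal(sum(tr$level12[tr$gene_id %in% grp] == "TE-free"), 0)
  cont <- build_contingency(tr, list(total = tr$gene_id, grp = grp))
  expect_lt(chi2_homogeneity(cont, "grp", "total")$p, bonferroni_alpha(1))
})
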