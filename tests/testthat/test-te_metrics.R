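test_that("gene vicinity extends by the flank and clamps to chromosome bounds", {
  v <- gene_vicinity(list(start = 5000, end = 8000), flank = 2000, chrom_length = 100000)
  expect_equal(unname(v), c(3000, 10000))
  expect_equal(gene_vicinity(list(start = 500, end = 1500), flank = 2000),
               c(start = 0, end = 3500))
  expect_equal(gene_vicinity(list(start = 500, end = 1500), flank = 0),
               c(start = 500, end = 1500))
  v2 <- gene_vicinity(list(start = 5000, end = 8000), flank = 2000, chrom_length = 9000)
  expect_equal(unname(v2), c(3000, 9000))
})

test_that("density and coverage follow their defining ratios", {
  # region [0, 5000): one SINE clipped to 500 bp
  gene <- make_genes(2000, 3000)
  te <- make_tes(4500, 5500)
  m <- te_metrics_for_gene(gene, te, flank = 2000)
  expect_equal(m$L_g, 5000)
  expect_equal(m$n_all, 1)
  expect_equal(m$lte_all, 500)
  expect_equal(m$coverage_all, 0.1)
  expect_equal(m$density_all, 1 / 4500)
  expect_equal(m$n_SINE, 1)
  expect_equal(m$coverage_LINE, 0)

  # no copies: the TE-free case
  m0 <- te_metrics_for_gene(gene, make_tes(integer(0), integer(0)), flank = 2000)
  expect_equal(m0$n_all, 0)
  expect_equal(m0$coverage_all, 0)
  expect_equal(m0$density_all, 0)

  # two overlapping LINEs: union length, not summed lengths
  m2 <- te_metrics_for_gene(gene, make_tes(c(1000, 1400), c(1600, 1800), "LINE"),
                            flank = 2000)
  expect_equal(m2$n_LINE, 2)
  expect_equal(m2$lte_LINE, 800)
  expect_equal(m2$coverage_all, 800 / 5000)
  expect_equal(m2$density_all, 2 / 4200)
})

test_that("nested copies count twice but cover once", {
  gene <- make_genes(2000, 3000)
  m <- te_metrics_for_gene(gene, make_tes(c(1000, 1200), c(2000, 1500), "LINE"),
                           flank = 2000)
  expect_equal(m$n_all, 2)
  expect_equal(m$lte_all, 1000) # outer copy only
})

test_that("coverage is invariant under copy splitting; density is not", {
  gene <- make_genes(2000, 3000)
  whole <- te_metrics_for_gene(gene, make_tes(1000, 1600), flank = 2000)
  split <- te_metrics_for_gene(gene, make_tes(c(1000, 1300), c(1300, 1600)),
                               flank = 2000)
  expect_equal(split$coverage_all, whole$coverage_all)
  expect_equal(split$lte_all, whole$lte_all)
  expect_equal(whole$n_all, 1)
  expect_equal(split$n_all, 2)
  expect_gt(split$density_all, whole$density_all)
})

test_that("metrics are invariant under a coordinate shift", {
  gene <- make_genes(20000, 23000)
  tes <- make_tes(c(19000, 21000, 24000), c(19500, 21800, 24400),
                  c("SINE", "LINE", "DNA"))
  shift <- 13579L
  gene2 <- gene; gene2$start <- gene$start + shift; gene2$end <- gene$end + shift
  tes2 <- tes; tes2$start <- tes$start + shift; tes2$end <- tes$end + shift
  m1 <- te_metrics_for_gene(gene, tes)
  m2 <- te_metrics_for_gene(gene2, tes2)
  drop_cols <- c("region_start", "region_end")
  expect_equal(m1[setdiff(names(m1), drop_cols)], m2[setdiff(names(m2), drop_cols)])
})

test_that("per-class covered lengths sum to at least the joint union", {
  set.seed(7)
  for (rep in 1:20) {
    gene <- make_genes(5000, 9000)
    k <- sample(1:8, 1)
    s <- sample(3000:10500, k)
    tes <- make_tes(s, s + sample(100:1500, k, replace = TRUE),
                    sample(c("DNA", "LTR", "LINE", "SINE"), k, replace = TRUE))
    m <- te_metrics_for_gene(gene, tes)
    class_sum <- m$lte_DNA + m$lte_LTR + m$lte_LINE + m$lte_SINE
    expect_gte(class_sum, m$lte_all)
    expect_equal(m$n_all, m$n_DNA + m$n_LTR + m$n_LINE + m$n_SINE)
  }
})

test_that("a fully TE-covered vicinity has undefined density but coverage 1", {
  gene <- make_genes(2000, 3000)
  m <- te_metrics_for_gene(gene, make_tes(0, 5000), flank = 2000)
  expect_equal(m$coverage_all, 1)
  expect_true(is.na(m$density_all))
})

test_that("metrics match a per-base brute-force oracle on randomized genes", {
  set.seed(11)
  for (rep in 1:50) {
    gstart <- sample(0:4000, 1)
    glen <- sample(500:4000, 1)
    gene <- make_genes(gstart, gstart + glen)
    k <- sample(0:8, 1)
    if (k > 0) {
      s <- sample(0:(gstart + glen + 3000), k, replace = TRUE)
      tes <- make_tes(s, s + sample(50:2000, k, replace = TRUE))
    } else {
      tes <- make_tes(integer(0), integer(0))
    }
    m <- te_metrics_for_gene(gene, tes, flank = 2000)
    o <- brute_gene_metrics(gene[1, ], tes, flank = 2000)
    expect_equal(m$L_g, o$L_g)
    expect_equal(m$n_all, o$n)
    expect_equal(m$lte_all, o$lte)
    expect_equal(m$coverage_all, o$coverage)
    expect_equal(m$density_all, o$density)
  }
})

test_that("spearman correlation of density and coverage behaves as expected", {
  mk <- function(d, c_) data.frame(gene_id = sprintf("G%d", seq_along(d)),
                                   density_all = d, coverage_all = c_)
  expect_equal(density_coverage_correlation(mk(1:3, 1:3))$rho, 1)
  expect_equal(density_coverage_correlation(mk(1:3, 3:1))$rho, -1)
  expect_true(is.na(density_coverage_correlation(mk(rep(1, 5), 1:5))$rho))
  expect_error(density_coverage_correlation(mk(1:2, 1:2)),
               class = "tenet_validation_error")
})

test_that("density and coverage are strongly rank-correlated on synthetic genomes", {
  sim <- simulate_genome(sim_config(seed = 3))
  m <- te_metrics(sim$genes, sim$tes, chrom_lengths = sim$chrom_lengths)
  cc <- density_coverage_correlation(m)
  expect_gt(cc$rho, 0.8)
  expect_lt(cc$p, 1e-10)
})
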