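test_that("unsatisfiable or inconsistent configurations are rejected upfront", {
  expect_error(sim_config(level3_fractions = c(free = 0.5, intermediate = 0.2, rich = 0.2)),
               class = "tenet_validation_error")
  expect_error(sim_config(coverage_ranges = list(intermediate = c(0.05, 0.15),
                                                 rich = c(0.95, 0.99))),
               class = "tenet_validation_error")
  expect_error(sim_config(per_class_coverage = list(intermediate = c(0.02, 0.05),
                                                    rich = c(0.3, 0.4))),
               class = "tenet_validation_error")
  expect_error(sim_config(de_coupling = 1.5), class = "tenet_validation_error")
  expect_error(sim_config(marks = "H9K99me9"), class = "tenet_validation_error")
})

test_that("the same seed reproduces byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_genome(sim_config(seed = 7), out_dir = d1)
  simulate_genome(sim_config(seed = 7), out_dir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 20) # gtf, te, chrom.sizes, de, truths, 20 broadPeaks
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_genome(sim_config(seed = 8), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "te.tsv")),
                         readLines(file.path(d3, "te.tsv"))))
})

test_that("emitted files parse through the package readers", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(sim_config(seed = 9), out_dir = d)
  genes <- read_gene_annotation(file.path(d, "genes.gtf"), "gtf")
  expect_equal(genes[c("gene_id", "chrom", "start", "end", "strand")],
               sim$genes[c("gene_id", "chrom", "start", "end", "strand")])
  tes <- read_repeatmasker_out(file.path(d, "te.tsv"), "tsv")
  expect_equal(nrow(tes), nrow(sim$tes))
  pk <- read_broadpeak(file.path(d, "H3K9ac_cancer.broadPeak"),
                       "H3K9ac", "cancer")
  ref <- sim$peaks[sim$peaks$mark == "H3K9ac" & sim$peaks$condition == "cancer", ]
  expect_equal(pk$signal, ref$signal)
  de <- read_de_table(file.path(d, "de.tsv"))
  expect_equal(de, sim$de)
  cs <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(cs, sim$chrom_lengths)
})

test_that("planted structure is realized exactly in the emitted data", {
  sim <- simulate_genome(sim_config(seed = 10))
  tr <- sim$truth$categories
  m <- te_metrics(sim$genes, sim$tes, chrom_lengths = sim$chrom_lengths)

  # TE-free genes have zero overlapping copies
  free <- tr$level3 == "TE-free"
  expect_true(all(m$n_all[free] == 0))

  # recomputed coverage equals the planted target up to bp rounding
  expect_lt(max(abs(m$coverage_all - tr$coverage_total)), 1e-3)

  # planted ranges are disjoint and honored
  inter <- tr$level3 == "TE-intermediate"
  rich <- tr$level3 == "TE-rich"
  expect_true(all(m$coverage_all[inter] > 0.04 & m$coverage_all[inter] < 0.16))
  expect_true(all(m$coverage_all[rich] > 0.44 & m$coverage_all[rich] < 0.61))

  # genes never overlap; TE copies stay within chromosome bounds
  for (cc in unique(sim$genes$chrom)) {
    g <- sim$genes[sim$genes$chrom == cc, ]
    g <- g[order(g$start), ]
    expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
  }
  expect_true(all(sim$tes$start >= 0))
  expect_true(all(sim$tes$end <= sim$chrom_lengths[sim$tes$chrom]))
})

test_that("the full pipeline recovers categories, shifts, and over-representation", {
  sim <- simulate_genome(sim_config(seed = 11))
  m <- te_metrics(sim$genes, sim$tes, chrom_lengths = sim$chrom_lengths)
  cl <- classify_genes(m)
  tr <- sim$truth$categories
  expect_gte(rand_index(cl$level3, tr$level3), 0.95)

  enr <- enrichment_matrix(sim$genes, sim$peaks)
  d <- differential_enrichment(enr, "normal", "cancer")
  sh <- sim$truth$shifts
  delta <- d$delta[match(paste(sh$gene_id, sh$mark),
                         paste(d$gene_id, d$mark))]
  # shifts are planted in the cancer condition; delta is normal - cancer
  expect_gte(mean(sign(-delta) == sign(sh$shift)), 0.95)

  d1 <- differential_enrichment(enr, "normal", "cancer", tau = 1)
  grp <- enrichment_direction_sets(d1, "H3K27me3", "enriched-in-B", tau = 1)
  cont <- build_contingency(cl, list(total_genome = cl$gene_id, shifted = grp))
  expect_lt(chi2_homogeneity(cont, "shifted", "total_genome")$p, bonferroni_alpha(1))
})
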