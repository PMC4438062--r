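test_that("no injected effects leaves an empty truth record", {
  sim <- generate_expression(tiny_map(), one_system_design(),
                             noise_sd = 0.2, seed = 3)
  expect_equal(nrow(sim$truth$de), 0)
  expect_equal(dim(sim$expr), c(50L, 12L))
})

test_that("injected effects move sample means by the stated log2 amount", {
  # many replicates so the mean difference concentrates on the effect
  des <- one_system_design(replicates = 30)
  map <- tiny_map()
  genes <- map$genes$gene_id[1:20]
  de <- data.frame(gene_id = genes, cell_line = "*", passage = "late",
                   log2fc = 2)
  sim <- generate_expression(map, des, de, noise_sd = 0.2, seed = 5)
  late <- sim$expr$samples$passage == "late"
  diff <- rowMeans(sim$expr$values[genes, late]) -
    rowMeans(sim$expr$values[genes, !late])
  expect_true(all(abs(diff - 2) < 3 * 0.2 / sqrt(30)))
})

test_that("cluster_spec plants the requested number of genes on the band", {
  map <- tiny_map()
  band <- map$genes$band[1]
  n_avail <- sum(map$genes$band == band)
  n <- min(5, n_avail)
  sim <- generate_expression(map, one_system_design(),
                             cluster_spec = data.frame(band = band, n = n,
                                                       direction = "up"),
                             noise_sd = 0.2, seed = 2)
  planted <- sim$truth$de[sim$truth$de$source == "cluster", ]
  expect_equal(nrow(planted), n)
  expect_true(all(map$genes$band[match(planted$gene_id,
                                       map$genes$gene_id)] == band))
  expect_true(all(planted$log2fc > 0))
})

test_that("expression generation is deterministic and validates inputs", {
  map <- tiny_map()
  des <- one_system_design()
  a <- generate_expression(map, des, noise_sd = 0.3, seed = 9)
  b <- generate_expression(map, des, noise_sd = 0.3, seed = 9)
  expect_identical(a, b)
  expect_error(generate_expression(map, des, noise_sd = 0, seed = 1),
               "noise_sd")
  expect_error(
    generate_expression(map, des,
                        de_spec = data.frame(gene_id = "nope",
                                             cell_line = "*",
                                             passage = "late", log2fc = 1),
                        seed = 1),
    "unknown gene")
  expect_error(
    generate_expression(map, des,
                        cluster_spec = data.frame(band = "zz", n = 2,
                                                  direction = "up"),
                        seed = 1),
    "cytoband")
})

test_that("truth bookkeeping counts every injected effect exactly once", {
  map <- tiny_map()
  de <- data.frame(gene_id = map$genes$gene_id[1:7], cell_line = "LM5",
                   passage = "*", log2fc = 1.5)
  band <- map$genes$band[nrow(map$genes)]
  n_cl <- min(3, sum(map$genes$band == band))
  sim <- generate_expression(map, one_system_design(), de,
                             cluster_spec = data.frame(band = band, n = n_cl,
                                                       direction = "down"),
                             seed = 4)
  expect_equal(nrow(sim$truth$de), 7 + n_cl)
})

test_that("coupling probability 0 and 1 give no and all coupling flags", {
  map <- tiny_map()
  des <- one_system_design()
  band <- map$cytobands$band[1]
  n_on_band <- sum(map$genes$band == band)
  ev <- data.frame(condition = "SAOS_late", band = band, chrom = NA,
                   start = NA, end = NA, state = "gain", n_probes = 200)
  cn0 <- generate_cn_profiles(map, des, ev, couple_prob = 0,
                              couple_effect = 1.5, seed = 1)
  expect_equal(nrow(cn0$truth$coupling), 0)
  cn1 <- generate_cn_profiles(map, des, ev, couple_prob = 1,
                              couple_effect = 1.5, seed = 1)
  # all genes with majority span inside the gained band are coupled
  expect_gt(nrow(cn1$truth$coupling), 0)
  expect_lte(abs(nrow(cn1$truth$coupling) - n_on_band), 1)
  expect_true(all(cn1$truth$coupling$state == "gain"))
  expect_true(all(cn1$truth$coupling$log2fc == 1.5))
})

test_that("coupling shifts the expression of the targeted condition", {
  map <- tiny_map()
  des <- one_system_design()
  base <- generate_expression(map, des, noise_sd = 0.25, seed = 6)
  ev <- data.frame(condition = "SAOS_late", chrom = "chr1", start = 0,
                   end = 5e6, state = "gain", n_probes = 500)
  cn <- generate_cn_profiles(map, des, ev, couple_prob = 1,
                             couple_effect = 2, seed = 7, expr = base$expr)
  coupled <- cn$truth$coupling$gene_id
  cols <- with(cn$expr$samples, sample[cell_line == "SAOS" & passage == "late"])
  shift <- cn$expr$values[coupled, cols] - base$expr$values[coupled, cols]
  expect_true(all(abs(shift - 2) < 1e-12))
  other <- setdiff(colnames(base$expr$values), cols)
  expect_identical(cn$expr$values[, other], base$expr$values[, other])
})

test_that("conflicting same-condition events are rejected", {
  map <- tiny_map()
  ev <- rbind(
    data.frame(condition = "SAOS_late", chrom = "chr1", start = 0,
               end = 2e6, state = "gain", n_probes = 100),
    data.frame(condition = "SAOS_late", chrom = "chr1", start = 1e6,
               end = 3e6, state = "loss", n_probes = 100))
  expect_error(generate_cn_profiles(map, one_system_design(), ev, seed = 1),
               "conflicting")
  expect_error(generate_cn_profiles(map, one_system_design(),
                                    ev[1, ], couple_prob = 2, seed = 1),
               "couple_prob")
})

test_that("null simulation: regulated_set flags about 5% of genes at p<0.05", {
  map <- generate_genome_map(4, 500, 4, seed = 21)
  sim <- generate_expression(map, one_system_design(), noise_sd = 0.3,
                             seed = 22)
  tab <- contrast(sim$expr, samples_for(sim$expr, "SAOS", "early"),
                  samples_for(sim$expr, "SAOS", "late"))
  frac <- mean(tab$p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / nrow(tab))
  expect_lt(abs(frac - 0.05), tol)
})
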