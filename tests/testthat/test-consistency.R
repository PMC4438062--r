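# Simulated system with metastatic-effect genes (both passages) and
# passage-effect genes (late samples of both lines).
consistency_sim <- function(seed, n_met = 12, n_pass = 12,
                            noise_sd = 0.25) {
  map <- tiny_map()
  ids <- map$genes$gene_id
  de <- rbind(
    data.frame(gene_id = ids[seq_len(n_met)], cell_line = "LM5",
               passage = "*", log2fc = 2),
    data.frame(gene_id = ids[n_met + seq_len(n_pass)], cell_line = "*",
               passage = "late", log2fc = 2))
  sim <- generate_expression(map, one_system_design(), de,
                             noise_sd = noise_sd, seed = seed)
  list(map = map, expr = sim$expr,
       met = ids[seq_len(n_met)], pass = ids[n_met + seq_len(n_pass)])
}

test_that("build_grid produces the four 3v3 contrasts plus a 6v6 pool", {
  sx <- consistency_sim(1)
  grid <- build_grid(sx$expr, "SAOS", "LM5")
  expect_named(grid$tables, c("ME_PE", "ML_PE", "ME_PL", "ML_PL"))
  for (tt in grid$tables) {
    expect_equal(attr(tt, "n_a"), 3L)
    expect_equal(attr(tt, "n_b"), 3L)
  }
  expect_equal(attr(grid$pooled, "n_a"), 6L)
  expect_equal(attr(grid$pooled, "n_b"), 6L)
  expect_error(build_grid(sx$expr, "SAOS", "HOS"), "ME")
})

test_that("pooled fold equals the mean of the four folds without passage effects", {
  # constructed noiseless-like case: only a metastatic effect
  vals <- matrix(8, nrow = 2, ncol = 12)
  samples <- data.frame(
    sample = paste0("s", 1:12),
    cell_line = rep(c("SAOS", "LM5"), each = 6),
    passage = rep(rep(c("early", "late"), each = 3), 2),
    replicate = rep(1:3, 4))
  vals[1, 7:12] <- 10                       # +2 in all metastatic samples
  colnames(vals) <- samples$sample
  rownames(vals) <- c("gA", "gB")
  grid <- build_grid(expression_matrix(vals, samples), "SAOS", "LM5")
  four <- vapply(grid$tables, function(tt) tt$log2fc[1], 0)
  expect_equal(unname(grid$pooled$log2fc[1]), mean(four), tolerance = 1e-6)
  # a gene with identical values everywhere has fold 0 in all five tables
  expect_true(all(abs(vapply(grid$tables,
                             function(tt) tt$log2fc[2], 0)) < 1e-9))
})

test_that("consistent_genes enforces pass counts and direction consistency", {
  mk_table <- function(lfc, p) {
    structure(data.frame(gene_id = paste0("g", seq_along(lfc)),
                         log2fc = lfc, t = 0, p = p, q = p),
              class = c("contrast_table", "data.frame"), n_a = 3L, n_b = 3L)
  }
  # g1: 4/4 up; g2: 3/4 up (one non-significant, same sign);
  # g3: 2 up + 2 down, all significant; g4: never passes
  lfc <- list(ME_PE = c(2, 2, 2, 0.1), ML_PE = c(2, 2, 2, 0.1),
              ME_PL = c(2, 2, -2, 0.1), ML_PL = c(2, 0.2, -2, 0.1))
  p <- list(ME_PE = c(0.01, 0.01, 0.01, 0.9),
            ML_PE = c(0.01, 0.01, 0.01, 0.9),
            ME_PL = c(0.01, 0.01, 0.01, 0.9),
            ML_PL = c(0.01, 0.5, 0.01, 0.9))
  grid <- structure(list(
    tables = Map(mk_table, lfc, p),
    pooled = mk_table(c(2, 2, 0, 0.1), c(0.01, 0.01, 1, 0.9)),
    parental = "P", metastatic = "M"), class = "comparison_grid")
  four <- consistent_genes(grid, min_pass = 4)
  expect_equal(four$gene_id, "g1")
  expect_equal(four$n_pass, 4L)
  three <- consistent_genes(grid, min_pass = 3)
  expect_setequal(three$gene_id, c("g1", "g2"))
  # reversed directions never reported, at either stringency
  expect_false("g3" %in% three$gene_id)
  # min_pass 4 results are a subset of min_pass 3 results
  expect_true(all(four$gene_id %in% three$gene_id))
  # mean fold averages the four signed linear folds
  expect_equal(four$mean_fold, 4)
  g2 <- three[three$gene_id == "g2", ]
  expect_equal(g2$mean_fold, mean(c(4, 4, 4, 2^0.2)))
  expect_error(consistent_genes(grid, min_pass = 2), "min_pass")
})

test_that("metastatic effects are kept and passage effects rejected at min_pass 4", {
  excluded <- 0L; kept <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sx <- consistency_sim(300 + r)
    grid <- build_grid(sx$expr, "SAOS", "LM5")
    genes <- consistent_genes(grid, min_pass = 4)
    kept <- kept + sum(sx$met %in% genes$gene_id)
    excluded <- excluded + sum(!(sx$pass %in% genes$gene_id))
  }
  expect_gte(kept / (20 * 12), 0.9)           # true metastatic signal recovered
  expect_gte(excluded / (20 * 12), 0.95)      # passage confounders rejected
})

test_that("the pooled contrast never yields fewer genes than the 4-way filter", {
  for (r in 1:3) {
    sx <- consistency_sim(500 + r)
    grid <- build_grid(sx$expr, "SAOS", "LM5")
    pooled <- regulated_set(grid$pooled, 2, 0.05, "p")
    n_pooled <- length(pooled$up) + length(pooled$down)
    expect_gte(n_pooled, nrow(consistent_genes(grid, min_pass = 4)))
  }
})

test_that("retention_pct reproduces the worked 14-of-56 example", {
  expect_equal(retention_pct(14, 56), 25)
  expect_error(retention_pct(1, 0), "n_pooled")
})

test_that("pathway_filter reports members, directions and enrichment", {
  genes <- data.frame(gene_id = paste0("g", 1:10),
                      direction = rep(c("up", "down"), 5),
                      n_pass = 4, mean_fold = 3)
  sets <- list(hit_set = c(paste0("g", 1:4), "x1", "x2"),
               miss_set = c("y1", "y2", "y3"))
  res <- pathway_filter(genes, sets, universe_n = 100)
  hit <- res[res$set == "hit_set", ]
  expect_equal(hit$n_members, 4)
  expect_equal(hit$n_up, 2)
  expect_equal(hit$n_down, 2)
  expect_equal(hit$ease_p, hyper_tail_oracle(3, 10, 6, 100))
  expect_equal(hit$fisher_p, hyper_tail_oracle(4, 10, 6, 100))
  miss <- res[res$set == "miss_set", ]
  expect_equal(miss$n_members, 0)
  expect_equal(miss$ease_p, 1)
  expect_equal(attr(res, "members")$hit_set, paste0("g", 1:4))
  expect_error(pathway_filter(genes, list(), 100), "non-empty")
})

test_that("cross_system_intersection performs exact set algebra", {
  res <- cross_system_intersection(list(A = c("a", "b", "c"),
                                        B = c("b", "c"), C = "c"))
  expect_equal(res$all, "c")
  expect_equal(res$pairwise[["A&B"]], c("b", "c"))
  expect_equal(res$pairwise[["B&C"]], "c")
  disjoint <- cross_system_intersection(list(A = "a", B = "b", C = "c"))
  expect_length(disjoint$all, 0)
  expect_true(all(lengths(disjoint$pairwise) == 0))
  same <- cross_system_intersection(list(A = "z", B = "z", C = "z"))
  expect_equal(same$all, "z")
  expect_error(cross_system_intersection(list(A = "a")), "two")
})
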