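test_that("gene module scores are centred for null modules and shifted for real ones", {
  set.seed(91)
  n_genes <- 200
  n_obs <- 100
  expr <- pmax(matrix(rnorm(n_genes * n_obs, 2, 0.5), n_genes, n_obs,
                      dimnames = list(paste0("g", 1:n_genes), NULL)), 0)
  module <- paste0("g", 1:10)
  s_null <- gene_module_score(expr, module, seed = 1)
  expect_lt(abs(mean(s_null)), 0.15)

  shifted <- expr
  shifted[module, ] <- shifted[module, ] + 1
  s_shift <- gene_module_score(shifted, module, seed = 1)
  expect_lt(abs(mean(s_shift) - 1), 0.2)

  expect_identical(gene_module_score(expr, module, seed = 7),
                   gene_module_score(expr, module, seed = 7))
  expect_error(gene_module_score(expr, character()), "empty")
  expect_error(gene_module_score(expr, "not_there"), "pool")
})

test_that("random gene-set scores are centred on zero", {
  set.seed(92)
  expr <- pmax(matrix(rnorm(300 * 50, 2, 0.5), 300, 50,
                      dimnames = list(paste0("g", 1:300), NULL)), 0)
  means <- replicate(50, {
    mod <- sample(rownames(expr), 15)
    mean(gene_module_score(expr, mod, seed = sample.int(1e4, 1)))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("regulatory module deviation tracks branch-specific openness", {
  set.seed(93)
  n_reg <- 120
  n_obs <- 80
  branchA <- seq_len(40)
  access <- matrix(runif(n_reg * n_obs, 0.3, 0.7), n_reg, n_obs,
                   dimnames = list(paste0("R", 1:n_reg), NULL))
  module <- paste0("R", 1:10)
  access[module, branchA] <- 0.95
  access[module, -branchA] <- 0.05
  z <- regulatory_module_deviation(access, module, seed = 1)
  expect_gt(mean(z[branchA]), 1)
  expect_lt(mean(z[-branchA]), -1)

  flat <- matrix(0.5, n_reg, n_obs, dimnames = list(paste0("R", 1:n_reg), NULL))
  flat <- flat + matrix(rnorm(n_reg * n_obs, 0, 0.01), n_reg, n_obs)
  flat <- pmin(pmax(flat, 0), 1)
  z0 <- regulatory_module_deviation(flat, module, seed = 1)
  expect_lt(max(abs(z0)), 3)

  expect_identical(regulatory_module_deviation(access, module, seed = 2),
                   regulatory_module_deviation(access, module, seed = 2))
  expect_error(regulatory_module_deviation(access, character()), "empty")
})

test_that("variance explained matches exact constructions and nests", {
  branch <- rep(c("A", "B"), each = 50)
  pt <- seq(0, 1, length.out = 100)
  expect_equal(unname(variance_explained(pt, branch, pt)["pseudotime"]), 1)
  expect_equal(unname(variance_explained(as.numeric(branch == "A"),
                                         branch, pt)["branch"]), 1)
  set.seed(94)
  noise <- rnorm(500)
  r2 <- variance_explained(noise, rep(c("A", "B"), 250),
                           seq(0, 1, length.out = 500))
  expect_true(all(r2 <= 0.05))
  # nesting: the joint model explains at least as much as each single one
  act <- rnorm(100) + pt + (branch == "A")
  r2 <- variance_explained(act, branch, pt)
  expect_gte(r2["both"], max(r2["branch"], r2["pseudotime"]) - 1e-10)
  expect_equal(unname(variance_explained(rep(1, 100), branch, pt)),
               c(0, 0, 0))
})

test_that("differential module activity ranks late-pseudotime shifts", {
  set.seed(95)
  n_obs <- 200
  branch <- rep(c("A", "B"), each = n_obs / 2)
  pt <- runif(n_obs)
  act <- matrix(rnorm(6 * n_obs), 6, n_obs,
                dimnames = list(paste0("m", 1:6), NULL))
  act[3, branch == "A"] <- act[3, branch == "A"] + 3   # strong up in A
  act[5, branch == "A"] <- act[5, branch == "A"] + 1.5 # weaker up in A
  res <- differential_module_activity(act, branch, pt,
                                      branches = c("A", "B"))
  up_a <- res[res$up_branch == "A", ]
  expect_equal(up_a$module[up_a$rank == 1], "m3")
  expect_true("m5" %in% up_a$module)
  expect_false("m1" %in% res$module)
  # top_k larger than qualifying modules returns all qualifying
  expect_lte(nrow(up_a), 15)
  expect_error(differential_module_activity(act, branch,
                                            ifelse(branch == "A", 0, 1),
                                            branches = c("A", "B")),
               "empty")
})

test_that("wilcoxon inside differential activity matches the exact test", {
  set.seed(96)
  act <- matrix(rnorm(3 * 20), 3, 20, dimnames = list(paste0("m", 1:3), NULL))
  branch <- rep(c("A", "B"), each = 10)
  pt <- runif(20)
  res <- differential_module_activity(act, branch, pt, quantile = 0.3,
                                      branches = c("A", "B"), fdr = 2)
  keep <- pt > stats::quantile(pt, 0.3)
  for (m in 1:3) {
    want <- stats::wilcox.test(act[m, keep & branch == "A"],
                               act[m, keep & branch == "B"])$p.value
    got <- unique(res$p[res$module == paste0("m", m)])
    if (length(got)) expect_equal(got, want)
  }
})

test_that("branch activation score is the z-scored mean gene correlation", {
  set.seed(97)
  prob <- runif(30)
  expr <- rbind(g1 = prob, g2 = prob, g3 = 1 - prob, g4 = 1 - prob,
                g5 = rep(0.5, 30))
  res <- branch_activation_score(expr, list(up = c("g1", "g2"),
                                            down = c("g3", "g4")), prob)
  expect_equal(unname(res$module_mean), c(1, -1))
  expect_equal(unname(res$score), c(1, -1) / sqrt(2), tolerance = 1e-12)

  # constant gene skipped and counted
  res2 <- branch_activation_score(expr, list(m = c("g1", "g5")), prob)
  expect_equal(unname(res2$n_skipped["m"]), 1L)
  expect_equal(unname(res2$module_mean["m"]), 1)

  spear <- branch_activation_score(expr, list(up = "g1"), prob,
                                   method = "spearman")
  expect_equal(unname(spear$module_mean), 1)
  expect_error(branch_activation_score(expr, list(m = "g1"), prob * 2),
               "\\[0, 1\\]")
})
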