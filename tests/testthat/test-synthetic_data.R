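test_that("noiseless target expression equals the generating model exactly", {
  sim <- simulate_regulome(n_tfs = 2, n_targets = 5, n_obs = 40,
                           noise_sd = 0, seed = 4, with_genome = FALSE,
                           closed_fraction = 0)
  e <- sim$paired$expression[sim$truth$tf_ids, ]
  a <- sim$paired$accessibility
  for (tg in sim$truth$target_ids) {
    w <- sim$truth$wiring[sim$truth$wiring$target == tg, ]
    mu <- rep(0, 40)
    for (k in seq_len(nrow(w))) {
      mu <- mu + w$beta[k] * e[w$tf[k], ] * a[w$region_id[k], ]
    }
    expect_equal(unname(sim$paired$expression[tg, ]), unname(pmax(0, mu)),
                 tolerance = 1e-12)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_regulome(n_tfs = 3, n_targets = 8, n_obs = 30, seed = 9,
                          with_genome = TRUE)
  s2 <- simulate_regulome(n_tfs = 3, n_targets = 8, n_obs = 30, seed = 9,
                          with_genome = TRUE)
  expect_identical(s1$paired$expression, s2$paired$expression)
  expect_identical(s1$truth$wiring, s2$truth$wiring)
  expect_identical(s1$genome, s2$genome)
  s3 <- simulate_regulome(n_tfs = 3, n_targets = 8, n_obs = 30, seed = 10,
                          with_genome = FALSE)
  expect_false(identical(s1$paired$expression, s3$paired$expression))
})

test_that("refitting the generating model recovers the coefficients", {
  sim <- simulate_regulome(n_tfs = 6, n_targets = 40, n_obs = 500,
                           noise_sd = 0.1, seed = 14, with_genome = FALSE)
  e <- sim$paired$expression[sim$truth$tf_ids, ]
  a <- sim$paired$accessibility
  # independent oracle: OLS on the known design per target
  w <- sim$truth$wiring
  beta_hat <- numeric(nrow(w))
  for (tg in unique(w$target)) {
    rows <- which(w$target == tg)
    X <- vapply(rows, function(k) e[w$tf[k], ] * a[w$region_id[k], ],
                numeric(500))
    fit <- stats::lm.fit(cbind(1, X), sim$paired$expression[tg, ])
    beta_hat[rows] <- fit$coefficients[-1]
  }
  expect_gt(stats::cor(beta_hat, w$beta), 0.95)
})

test_that("wired regions carry the wired TF's motif inside the region", {
  sim <- simulate_regulome(n_tfs = 4, n_targets = 10, n_obs = 20, seed = 2,
                           with_genome = TRUE, region_len = 150,
                           motif_len = 12)
  plc <- sim$truth$placements
  w <- sim$truth$wiring
  has_plc <- mapply(function(tf, rid) {
    any(plc$tf == tf & plc$region_id == rid)
  }, w$tf, w$region_id)
  expect_true(all(has_plc))
  # planted consensus is literally in the genome at the recorded offset
  for (i in seq_len(nrow(plc))) {
    r <- sim$regions[match(plc$region_id[i], sim$regions$region_id), ]
    cons <- sim$truth$consensi[[plc$tf[i]]]
    found <- substr(sim$genome[[r$chrom]], r$start + plc$offset[i] + 1,
                    r$start + plc$offset[i] + nchar(cons))
    if (plc$strand[i] == "-") {
      found <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(found)))
    }
    expect_equal(found, cons)
  }
  expect_error(simulate_regulome(n_tfs = 2, n_targets = 2, n_obs = 5,
                                 region_len = 5, motif_len = 10),
               "infeasible")
})

test_that("closed regions have zero accessibility in their branch", {
  sim <- simulate_regulome(n_tfs = 5, n_targets = 30, n_obs = 200, seed = 6,
                           with_genome = FALSE, closed_fraction = 0.2)
  closed <- sim$truth$branch_closed_regions
  expect_gt(sum(lengths(closed)), 0)
  br <- sim$paired$obs_meta$branch
  for (b in names(closed)) {
    for (rid in closed[[b]]) {
      expect_true(all(sim$paired$accessibility[rid, br == b] == 0))
      expect_gt(mean(sim$paired$accessibility[rid, br != b]), 0)
    }
  }
})

test_that("screen counts are bimodal and the separable mixture is recovered", {
  scr <- simulate_screen(300, targets = c("T1", "T2"), seed = 3)
  stopifnot(any(scr$counts > 0))
  X <- suppressWarnings(assign_guides(scr$counts, seed = 1))
  truthX <- outer(scr$truth$true_guide, colnames(scr$counts), "==") * 1L
  expect_gte(mean(X[truthX == 1] == 1), 0.99)
  expect_lte(mean(X[truthX == 0] == 1), 0.01)
})

test_that("escaper fraction is honoured within binomial error", {
  scr <- simulate_screen(2000, targets = c("T1", "T2", "T3"),
                         effect_sizes = list(
                           T1 = list(branch = "dorsal", lor = 1,
                                     expr_effect = 1),
                           T2 = list(branch = "ventral", lor = 1,
                                     expr_effect = 1)),
                         escaper_frac = 0.3, seed = 8)
  frac <- mean(scr$truth$escaper)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  # escapers carry no expression shift: their effect genes look baseline
  eg <- scr$truth$effect_genes$T1
  esc <- scr$truth$true_target == "T1" & scr$truth$escaper
  pert <- scr$truth$true_target == "T1" & scr$truth$perturbed
  null_cells <- !scr$truth$true_target %in% c("T1", "T2")
  expect_lt(abs(mean(scr$expression[eg, esc]) -
                  mean(scr$expression[eg, null_cells])), 0.1)
  expect_gt(mean(scr$expression[eg, pert]) -
              mean(scr$expression[eg, null_cells]), 0.3)
})

test_that("null screen composition is independent of guides", {
  scr <- simulate_screen(1000, targets = c("T1", "T2", "T3"), seed = 12)
  tab <- table(scr$truth$true_target, scr$obs_meta$branch)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
  expect_error(simulate_screen(100, targets = "T1",
                               effect_sizes = list(BAD = list())),
               "unknown target")
})
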