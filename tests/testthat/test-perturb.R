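test_that("guide assignment separates a well-split mixture exactly", {
  counts <- matrix(0L, 6, 2, dimnames = list(paste0("c", 1:6),
                                             c("g1", "g2")))
  counts[, 1] <- c(1L, 1L, 2L, 50L, 60L, 55L)
  counts[, 2] <- c(55L, 60L, 50L, 2L, 1L, 1L)
  x <- suppressWarnings(assign_guides(counts, seed = 1))
  expect_equal(unname(x[, 1]), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(unname(x[, 2]), c(1L, 1L, 1L, 0L, 0L, 0L))
  # zero counts never receive a guide
  expect_true(all(x[counts == 0] == 0))
})

test_that("degenerate counts fall back to a fixed threshold with a warning", {
  counts <- matrix(c(5L, 5L, 5L, 5L, 0L, 0L), 3, 2)
  expect_warning(x <- assign_guides(counts), "threshold")
  expect_true(all(x[counts == 0] == 0))
})

test_that("guide assignment is invariant to relabelling and seed-stable", {
  set.seed(101)
  counts <- matrix(0L, 60, 3)
  counts[cbind(1:60, sample(1:3, 60, TRUE))] <-
    as.integer(round(exp(rnorm(60, 4, 0.4))))
  counts[sample(which(counts == 0), 20)] <-
    as.integer(round(exp(rnorm(20, 0.5, 0.3)))) + 1L
  x1 <- assign_guides(counts, seed = 1)
  x2 <- assign_guides(counts, seed = 1)
  expect_identical(x1, x2)
  perm_cells <- sample(nrow(counts))
  perm_guides <- sample(ncol(counts))
  xp <- assign_guides(counts[perm_cells, perm_guides], seed = 1)
  expect_identical(unname(xp), unname(x1[perm_cells, perm_guides]))
})

test_that("perturbation probabilities separate perturbed from escaper cells", {
  scr <- simulate_screen(800, targets = c("T1", "T2", "T3"),
                         effect_sizes = list(
                           T1 = list(branch = "dorsal", lor = 0,
                                     expr_effect = 1.5)),
                         escaper_frac = 0.3, seed = 7)
  X <- assign_guides(scr$counts, seed = 1)
  pp <- perturbation_probability(
    scr$expression, X,
    scr$obs_meta[, c("n_features", "organoid", "cell_type")],
    guide_map = scr$guide_map, seed = 1)
  expect_true(all(pp$p[!is.na(pp$p) & X == 0] == 0))
  expect_true(all(pp$p[!is.na(pp$p)] >= 0 & pp$p[!is.na(pp$p)] <= 1))
  # target-level probability is the max over that target's guides
  g_t1 <- scr$guide_map$guide[scr$guide_map$target == "T1"]
  expect_equal(unname(pp$p_target[, "T1"]),
               unname(apply(pp$p[, g_t1], 1, max)))
  carriers <- scr$truth$true_target == "T1"
  p_cell <- pp$p_target[, "T1"]
  auc_lab <- scr$truth$perturbed[carriers]
  pv <- p_cell[carriers]
  r <- rank(pv)
  auroc <- (sum(r[auc_lab]) - sum(auc_lab) * (sum(auc_lab) + 1) / 2) /
    (sum(auc_lab) * sum(!auc_lab))
  expect_gt(auroc, 0.8)
})

test_that("guides with too few carriers are reported as missing", {
  set.seed(102)
  Y <- matrix(rnorm(40 * 60, 2), 40, 60,
              dimnames = list(paste0("g", 1:40), NULL))
  X <- matrix(0L, 60, 2, dimnames = list(NULL, c("gA", "gB")))
  X[1:30, 1] <- 1L
  X[31:32, 2] <- 1L  # only 2 carriers
  pp <- perturbation_probability(pmax(Y, 0), X,
                                 data.frame(n_features = rnorm(60, 100, 5)),
                                 min_cells = 5, seed = 1)
  expect_true(all(is.na(pp$p[, "gB"])))
  expect_false(anyNA(pp$p[, "gA"]))
})

test_that("KO transcriptomic effects find planted shifts and respect nulls", {
  set.seed(103)
  n_cells <- 300
  p_target <- cbind(T1 = rep(0, n_cells))
  pert <- sample(n_cells, 120)
  p_target[pert, "T1"] <- runif(120, 0.8, 1)
  Y <- matrix(rnorm(30 * n_cells, 2, 0.3), 30, n_cells,
              dimnames = list(paste0("g", 1:30), NULL))
  Y["g1", pert] <- Y["g1", pert] - 0.5
  res <- ko_transcriptomic_effects(pmax(Y, 0), p_target,
                                   data.frame(n_features =
                                                rnorm(n_cells, 100, 10)),
                                   fdr = 1e-4)
  tab <- res$table
  expect_true(tab$de[tab$gene == "g1"])
  expect_lt(tab$coefficient[tab$gene == "g1"], 0)
  expect_lt(sum(tab$de), 3)

  # collinear covariate columns are dropped and logged
  covar <- data.frame(a = rnorm(n_cells))
  covar$b <- 2 * covar$a
  res2 <- ko_transcriptomic_effects(pmax(Y, 0), p_target, covar)
  expect_equal(res2$aliased, "b")
})

test_that("CMH equals the closed form and the reference implementation", {
  balanced <- matrix(c(5, 5, 5, 5), 2, 2)
  res <- cmh_test(balanced)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # K = 1 reduces to the unstratified closed form
  t1 <- matrix(c(12, 5, 6, 14), 2, 2, byrow = TRUE)
  res1 <- cmh_test(t1)
  n <- sum(t1)
  e <- sum(t1[1, ]) * sum(t1[, 1]) / n
  v <- sum(t1[1, ]) * sum(t1[2, ]) * sum(t1[, 1]) * sum(t1[, 2]) /
    (n^2 * (n - 1))
  expect_equal(res1$statistic, (t1[1, 1] - e)^2 / v, tolerance = 1e-12)

  # stratified case against stats::mantelhaen.test
  set.seed(104)
  arr <- array(rpois(2 * 2 * 3, 15) + 1, c(2, 2, 3))
  arr[1, 1, ] <- arr[1, 1, ] + 10
  want <- stats::mantelhaen.test(arr, correct = FALSE)
  got <- cmh_test(arr)
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-8)
  expect_equal(got$p, want$p.value, tolerance = 1e-8)

  expect_equal(cmh_test(array(0, c(2, 2, 2)))$p, 1)
})

test_that("log odds ratio evaluates the printed formula with correction", {
  expect_equal(log_odds_ratio(10, 90, 5, 195), log((10 / 90) / (5 / 195)),
               tolerance = 1e-12)
  expect_equal(log_odds_ratio(10, 90, 5, 195), 1.466, tolerance = 1e-3)
  # Haldane-Anscombe: zero cells get +0.5 everywhere
  expect_equal(log_odds_ratio(0, 10, 5, 5),
               log((0.5 / 10.5) / (5.5 / 5.5)))
  expect_true(is.finite(log_odds_ratio(0, 0, 0, 0)))
})

test_that("composition filters drop inconsistent and unconfirmed guides", {
  set.seed(105)
  n <- 3000
  organoid <- paste0("org", sample(1:4, n, TRUE))
  branch <- sample(c("A", "B", "C"), n, TRUE)
  X <- matrix(0L, n, 4,
              dimnames = list(NULL, c("hit_g1", "hit_g2", "lone_g1",
                                      "orgonly_g1")))
  guide_map <- data.frame(guide = colnames(X),
                          target = c("HIT", "HIT", "LONE", "ORGONLY"))
  carrier <- split(sample(n, 1200), rep(1:4, each = 300))
  for (j in 1:4) X[carrier[[j]], j] <- 1L
  # both HIT guides enriched in branch A everywhere
  for (j in 1:2) {
    idx <- carrier[[j]]
    branch[idx] <- sample(c("A", "B", "C"), 300, TRUE,
                          prob = c(0.75, 0.125, 0.125))
  }
  # ORGONLY enriched in branch A only inside organoid 1
  idx <- carrier[[4]][organoid[carrier[[4]]] == "org1"]
  branch[idx] <- "A"
  res <- composition_enrichment(X, branch, organoid, guide_map)
  expect_true(all(c("hit_g1", "hit_g2") %in% res$kept_guides))
  expect_false("lone_g1" %in% res$kept_guides)   # no confirming mate
  expect_false("orgonly_g1" %in% res$kept_guides)  # single-organoid effect
  expect_equal(names(which.max(res$max_lor)), "HIT")
  tt <- res$target_table
  expect_equal(tt$branch[which.max(tt$lor)], "A")
})
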