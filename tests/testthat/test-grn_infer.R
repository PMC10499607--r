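make_toy_data <- function(e, a, y = NULL, target = "G1") {
  expr <- rbind(TF1 = e, if (!is.null(y)) y)
  if (!is.null(y)) rownames(expr)[2] <- target
  paired_matrix(expr, matrix(a, 1, length(a),
                             dimnames = list("R1", NULL)))
}

test_that("design columns are expression-accessibility products", {
  data <- make_toy_data(e = c(1, 2), a = c(0.5, 1), y = c(0, 0))
  pairs <- data.frame(gene_id = "G1", region_id = "R1")
  sites <- data.frame(region_id = "R1", tf = "TF1")
  dm <- build_design("G1", pairs, sites, data, min_detect = 0)
  expect_equal(as.numeric(dm$design), c(0.5, 2))
  expect_equal(dm$terms$tf, "TF1")

  # self-loop: the target's own motif term is absent
  sites_self <- data.frame(region_id = "R1", tf = c("TF1", "G1"))
  dm2 <- build_design("G1", pairs, sites_self, data, min_detect = 0)
  expect_equal(nrow(dm2$terms), 1)

  # two motifs of the same TF in one region collapse to one column
  sites_dup <- data.frame(region_id = c("R1", "R1"), tf = "TF1")
  dm3 <- build_design("G1", pairs, sites_dup, data, min_detect = 0)
  expect_equal(ncol(dm3$design), 1)

  # no surviving terms is a no-model outcome, not an error
  dm4 <- build_design("G1", pairs, sites[0, ], data)
  expect_true(dm4$no_model)
})

test_that("TF detection filter drops near-constant regulators", {
  n <- 100
  e_rare <- c(rep(0, 97), 1, 1, 1)      # 3% detection
  expr <- rbind(TF1 = e_rare, G1 = rnorm(n, 2))
  expr <- pmax(expr, 0)
  data <- paired_matrix(expr, matrix(0.5, 1, n, dimnames = list("R1", NULL)))
  pairs <- data.frame(gene_id = "G1", region_id = "R1")
  sites <- data.frame(region_id = "R1", tf = "TF1")
  expect_true(build_design("G1", pairs, sites, data, min_detect = 0.05)$no_model)
  expect_false(build_design("G1", pairs, sites, data, min_detect = 0.01)$no_model)
})

test_that("the default fit recovers noiseless coefficients and flags nulls", {
  set.seed(51)
  x1 <- rnorm(100)
  x2 <- rnorm(100)  # independent of y
  y <- 2 * x1
  design <- cbind(`TF1|R1` = x1, `TF2|R2` = x2)
  fit <- fit_target_model(y, design)
  expect_equal(fit$coef$beta[1], 2, tolerance = 1e-10)
  expect_lt(abs(fit$coef$beta[2]), 1e-10)
  expect_gt(fit$coef$pval[2], 0.5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equation solution", {
  set.seed(52)
  design <- matrix(rnorm(200 * 5), 200, 5,
                   dimnames = list(NULL, paste0("T", 1:5, "|R", 1:5)))
  y <- rnorm(200)
  fit <- fit_target_model(y, design)
  X <- cbind(1, design)
  want <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coef$beta, as.numeric(want[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, want[1], tolerance = 1e-8)
})

test_that("aliased design columns are dropped deterministically", {
  set.seed(53)
  x <- rnorm(50)
  design <- cbind(`A|R1` = x, `B|R2` = x)  # duplicated column
  fit <- fit_target_model(rnorm(50), design)
  expect_equal(fit$dropped, "B|R2")
  expect_equal(fit$coef$term, "A|R1")

  expect_error(fit_target_model(rnorm(3), matrix(rnorm(9), 3, 3)),
               "more observations")
})

test_that("regularized back-ends return coefficients without p-values", {
  set.seed(54)
  design <- matrix(rnorm(120 * 3), 120, 3,
                   dimnames = list(NULL, paste0("T", 1:3, "|R", 1:3)))
  y <- design %*% c(2, 0, -1) + rnorm(120, 0, 0.1)
  fit <- fit_target_model(as.numeric(y), design, method = "elastic_net")
  expect_true(all(is.na(fit$coef$pval)))
  expect_equal(sign(fit$coef$beta[c(1, 3)]), c(1, -1))
})

test_that("infer_grn pools p-values, respects the FDR threshold monotonically", {
  sim <- simulate_regulome(n_tfs = 5, n_targets = 30, n_obs = 200,
                           noise_sd = 0.1, seed = 61, with_genome = FALSE)
  g1 <- infer_grn(sim$paired, sim$sites, sim$gene_pairs, fdr_threshold = 0.01)
  g2 <- infer_grn(sim$paired, sim$sites, sim$gene_pairs, fdr_threshold = 0.10)
  key <- function(g) paste(g$edges$tf, g$edges$region_id, g$edges$target)
  expect_true(all(key(g1) %in% key(g2)))

  # BH fdr is non-decreasing in p-value rank
  ord <- order(g2$all_edges$pval)
  expect_true(all(diff(cummax(g2$all_edges$fdr[ord])) >= 0))

  g0 <- infer_grn(sim$paired, sim$sites, sim$gene_pairs, fdr_threshold = 0)
  expect_equal(nrow(g0$edges), 0)

  # modules: split by sign, disjoint, each member backed by an edge
  for (m in g2$modules) {
    expect_length(intersect(m$positive_targets, m$negative_targets), 0)
    for (tg in m$positive_targets) {
      expect_true(any(g2$edges$tf == m$tf & g2$edges$target == tg &
                        g2$edges$beta > 0))
    }
  }
  expect_false(any(g2$edges$tf == g2$edges$target))
})

test_that("shuffling the response breaks edges down to the null level", {
  sim <- simulate_regulome(n_tfs = 5, n_targets = 50, n_obs = 300,
                           noise_sd = 0.1, seed = 62, with_genome = FALSE)
  perm <- sim$paired
  set.seed(1)
  shuffled <- perm$expression
  for (tg in sim$truth$target_ids) {
    shuffled[tg, ] <- sample(shuffled[tg, ])
  }
  perm$expression <- shuffled
  g <- infer_grn(perm, sim$sites, sim$gene_pairs)
  expect_lte(length(unique(g$edges$target)), 0.07 * 50)
})

test_that("TF activity is mean coefficient times mean branch expression", {
  grn <- structure(list(edges = data.frame(
    tf = c("TF1", "TF1", "TF2"), region_id = c("R1", "R2", "R3"),
    target = c("G1", "G2", "G3"), beta = c(1, 3, -2),
    pval = 0.001, fdr = 0.01)), class = "grn")
  expr <- matrix(2, 3, 4, dimnames = list(c("TF1", "TF2", "G1"), NULL))
  act <- tf_activity_in_branch(grn, expr)
  expect_equal(unname(act["TF1"]), 4)   # mean(1,3) * 2
  expect_equal(unname(act["TF2"]), -4)  # -2 * 2
  expr0 <- expr
  expr0["TF1", ] <- 0
  expect_equal(unname(tf_activity_in_branch(grn, expr0)["TF1"]), 0)
  # a TF absent from the branch expression is absent from the output
  act2 <- tf_activity_in_branch(grn, expr[c("TF1", "G1"), ])
  expect_false("TF2" %in% names(act2))
})

test_that("region_map routes accessibility through enclosing peaks", {
  e <- c(1, 2, 3, 1)
  expr <- rbind(TF1 = e, G1 = c(0.5, 1, 1.5, 0.5))
  access <- matrix(c(0.2, 0.4, 0.6, 0.8), 1, 4, dimnames = list("pk1", NULL))
  data <- paired_matrix(expr, access)
  pairs <- data.frame(gene_id = "G1", region_id = "cand1")
  sites <- data.frame(region_id = "cand1", tf = "TF1")
  dm <- build_design("G1", pairs, sites, data, min_detect = 0,
                     region_map = c(cand1 = "pk1"))
  expect_equal(as.numeric(dm$design), e * c(0.2, 0.4, 0.6, 0.8))
})
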