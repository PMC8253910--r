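toy_design <- function() {
  data.frame(group = rep(c("A", "B"), each = 4),
             timepoint = rep(c("t1", "t2"), 4))
}
toy_values <- c(1, 2, 3, 4, 5, 6, 7, 8)  # cells {1,3},{2,4},{5,7},{6,8}

test_that("two-way ANOVA matches the hand decomposition on the 2x2 toy", {
  a <- anova_two_way(toy_values, toy_design())
  expect_equal(unname(a$ss), c(32, 2, 0))
  expect_equal(unname(a$F), c(16, 1, 0))
  expect_equal(unname(a$p), c(0.0161, 0.3739, 1),
               tolerance = 1e-3)
  expect_equal(unname(a$df), c(1, 1, 1))
  expect_equal(a$dfe, 4)
  expect_equal(a$mse, 2)

  # balanced-design identity: SS_total decomposes exactly
  ss_total <- sum((toy_values - mean(toy_values))^2)
  expect_equal(sum(a$ss) + a$sse, ss_total, tolerance = 1e-12)

  # location invariance and within-cell exchangeability
  b <- anova_two_way(toy_values + 100, toy_design())
  expect_equal(b$F, a$F)
  expect_equal(b$p, a$p)
  perm <- c(3, 2, 1, 4, 7, 6, 5, 8)  # swap within cells
  expect_equal(anova_two_way(toy_values[perm],
                             toy_design()[perm, ])$p, a$p)

  expect_error(anova_two_way(1:6,
    data.frame(group = c("A", "A", "A", "A", "B", "B"),
               timepoint = c("t1", "t1", "t2", "t2", "t1", "t1"))),
    "empty|>= 2")
})

test_that("Type-II ANOVA agrees with lm model comparison on unbalanced data", {
  d <- study_design()
  set.seed(2)
  for (i in 1:10) {
    y <- rnorm(nrow(d), sd = 1 + i / 10)
    a <- anova_two_way(y, d)
    df <- data.frame(y = y, g = d$group, t = d$timepoint)
    r <- function(f) sum(residuals(lm(f, data = df))^2)
    expect_equal(unname(a$ss),
                 c(r(y ~ t) - r(y ~ g + t), r(y ~ g) - r(y ~ g + t),
                   r(y ~ g + t) - r(y ~ g * t)),
                 tolerance = 1e-9)
    expect_equal(a$sse, r(y ~ g * t), tolerance = 1e-9)
  }
  # Type I and III available and consistent where the design is balanced
  db <- generate_design(5, dropout = character())
  yb <- rnorm(nrow(db))
  expect_equal(anova_two_way(yb, db, ss_type = "I")$ss,
               anova_two_way(yb, db, ss_type = "II")$ss,
               tolerance = 1e-9)
  expect_equal(anova_two_way(yb, db, ss_type = "III")$ss,
               anova_two_way(yb, db, ss_type = "II")$ss,
               tolerance = 1e-9)
})

test_that("Tukey HSD matches stats::TukeyHSD and the hand oracle", {
  d <- study_design()
  set.seed(5)
  y <- rnorm(nrow(d))
  mine <- tukey_hsd(y, d)
  ref <- TukeyHSD(aov(y ~ cell,
                      data = data.frame(cell = interaction(d$group,
                                                           d$timepoint))))[[1]]
  key_mine <- paste(mine$cell_a, mine$cell_b)
  expect_equal(nrow(mine), 15)
  expect_equal(sort(mine$adjusted_p), sort(unname(ref[, "p adj"])),
               tolerance = 1e-9)

  # degenerate one-way case, hand oracle: cells {1,2},{1,2},{5,6}
  # extreme-pair mean difference 4.0, MSE 0.5, q = 4/sqrt(0.5/2) = 8
  d2 <- data.frame(group = rep("G", 6),
                   timepoint = rep(c("c1", "c2", "c3"), each = 2))
  tk <- tukey_hsd(c(1, 2, 1, 2, 5, 6), d2)
  extreme <- tk[tk$cell_a == "G:c1" & tk$cell_b == "G:c3", ]
  expect_equal(extreme$q, 8)
  expect_equal(extreme$adjusted_p,
               ptukey(8, 3, 3, lower.tail = FALSE), tolerance = 1e-12)
  same <- tk[tk$cell_a == "G:c1" & tk$cell_b == "G:c2", ]
  expect_equal(same$mean_difference, 0)
  expect_equal(same$adjusted_p, 1)

  # monotone: larger |q| never gives larger adjusted p
  o <- order(tk$q)
  expect_true(all(diff(tk$adjusted_p[o]) <= 1e-12))
})

test_that("spline studentized-range tail matches ptukey", {
  f <- miprot:::tukey_tail_fun(6, 22)
  q <- c(0.1, 0.5, 1, 2, 3, 4.5, 6, 8, 12, 20)
  expect_equal(f(q), ptukey(q, 6, 22, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("BH adjustment matches the hand rule and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  }
})

test_that("geometric pooling follows the closed form", {
  expect_equal(pool_geometric(c(0.05, 0.05, 0.05)), 0.05)
  expect_equal(pool_geometric(c(1e-2, 1e-4)), 1e-3)
  set.seed(3)
  p <- runif(20)
  expect_gte(pool_geometric(p), min(p))
  expect_lte(pool_geometric(p), max(p))
  expect_error(pool_geometric(numeric(0)), "empty")
  expect_warning(out <- pool_geometric(c(0, 0.1)), "floored")
  expect_equal(out, sqrt(1e-300 * 0.1))
})

test_that("call_de recovers a strong planted effect with the right labels", {
  cfg <- generator_config(n_proteins = 60, de_fraction = 2 / 60,
                          effect_size_log2 = 4, noise_sd = 0.4,
                          missing_target_fraction = 0.1, seed = 19)
  sim <- simulate_proteomics(cfg)
  m <- intensity_matrix(sim$matrix[sim$truth$protein_id, , drop = FALSE],
                        sim$design)
  ens <- build_ensemble(m, n_replicates = 10, master_seed = 2)
  de <- call_de(ens)
  truth_idx <- which(sim$truth$is_de)
  expect_true(all(de$significant[truth_idx]))
  expect_equal(de$timepoint_of_significance[truth_idx], c("POD3", "POD3"))
  expect_equal(de$direction[truth_idx], c("NEVKP", "NEVKP"))
  # significant implies labels set (type invariant)
  expect_true(all(!is.na(de$timepoint_of_significance[de$significant])))
  expect_true(all(!is.na(de$direction[de$significant])))
  expect_true(all(de$q_interaction[de$significant] < 0.05))
})

test_that("pooled q-values stabilize as the ensemble grows", {
  cfg <- generator_config(n_proteins = 40, de_fraction = 0.2,
                          effect_size_log2 = 3, seed = 6)
  sim <- simulate_proteomics(cfg)
  x <- intensity_matrix(sim$matrix[sim$truth$protein_id, , drop = FALSE],
                        sim$design)
  ens300 <- build_ensemble(x, n_replicates = 300, master_seed = 9)
  ens150 <- ens300
  ens150$replicates <- ens300$replicates[1:150]
  ens150$replicate_seeds <- ens300$replicate_seeds[1:150]
  q300 <- call_de(ens300)$q_interaction
  q150 <- call_de(ens150)$q_interaction
  sel <- q300 < 0.2
  expect_gt(sum(sel), 0)
  expect_lt(median(abs(q150[sel] / q300[sel] - 1)), 0.1)
  # full stated ensemble size is supported
  expect_length(ens300$replicates, 300)
})
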