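test_that("generate_design reproduces the 28-of-30 layout and cell tallies", {
  d <- generate_design(5)
  expect_s3_class(d, "sample_design")
  expect_equal(nrow(d), 28)
  tab <- table(d$group, d$timepoint)
  expect_equal(unname(tab["NEVKP", ]), c(4, 4, 5))
  expect_equal(unname(tab["SCS", ]), c(5, 5, 5))
  expect_equal(nrow(generate_design(2, dropout = character())), 12)

  # brute-force tally over the design grid: removing 2 of a 3-sample cell
  # leaves a valid size-1 cell; emptying a cell is rejected
  d3 <- generate_design(3, dropout = c("NEVKP1_BL", "NEVKP2_BL"))
  expect_equal(sum(d3$group == "NEVKP" & d3$timepoint == "BL"), 1)
  expect_error(
    generate_design(2, dropout = c("NEVKP1_BL", "NEVKP2_BL")),
    "degenerate cell")
  expect_error(generate_design(5, dropout = "NOPE_BL"), "not in")
})

test_that("design invariants are enforced", {
  d <- generate_design(3, dropout = character())
  expect_silent(validate_design(d, strict = TRUE))
  d2 <- d
  d2$group[d2$animal_id == "NEVKP1"][1] <- "SCS"
  expect_error(validate_design(d2), "constant within animal")
  d3 <- rbind(d, d[1, ])
  expect_error(validate_design(d3), "duplicate")
})

test_that("generate_dataset honours truth bookkeeping and determinism", {
  cfg <- generator_config(n_proteins = 100, de_fraction = 0.13, seed = 5)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$truth$is_de), round(0.13 * 100))

  cfg0 <- generator_config(n_proteins = 50, de_fraction = 0, seed = 5)
  expect_equal(sum(generate_dataset(cfg0)$truth$is_de), 0)

  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$latent, b$latent)
  expect_identical(a$annotations, b$annotations)
})

test_that("with zero effects, cell means match the base abundance", {
  # Monte-Carlo mean versus closed form: many proteins share the generator,
  # so per-cell averages of (latent - base) estimate the injected effects.
  cfg <- generator_config(n_proteins = 10000, de_fraction = 0,
                          effect_size_log2 = 0, seed = 9)
  ds <- generate_dataset(cfg)
  centered <- ds$latent - ds$truth$base_log2
  cells <- interaction(ds$design$group, ds$design$timepoint)
  for (cl in levels(cells)) {
    v <- centered[, cells == cl, drop = FALSE]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v)), 4 * se + 1e-12)
  }
})

test_that("MNAR censoring follows the logistic curve", {
  set.seed(1)
  m <- matrix(rnorm(20000, 25, 2), nrow = 200)
  expect_error(apply_mnar_censoring(m, censor_location = 22,
                                    censor_scale = 0), "censor_scale")
  none <- apply_mnar_censoring(m, censor_location = -Inf, censor_scale = 1)
  expect_false(anyNA(none))

  flat <- matrix(22, 100, 100)
  cen <- apply_mnar_censoring(flat, censor_location = 22, censor_scale = 1,
                              seed = 3)
  se <- sqrt(0.25 / length(flat))
  expect_lt(abs(mean(is.na(cen)) - 0.5), 3 * se)

  # empirical missing fraction vs numerical integration of the N(25,2)
  # density against the logistic censoring curve
  target <- stats::integrate(function(x)
    stats::dnorm(x, 25, 2) * stats::plogis((22 - x) / 1), -Inf, Inf)$value
  cen2 <- apply_mnar_censoring(m, censor_location = 22, censor_scale = 1,
                               seed = 7)
  frac <- mean(is.na(cen2))
  se2 <- sqrt(target * (1 - target) / length(m))
  expect_lt(abs(frac - target), 3 * se2)

  # intensity dependence: censored latent values are lower on average
  expect_lt(mean(m[is.na(cen2)]), mean(m[!is.na(cen2)]))

  # seeded reproducibility
  expect_identical(cen2, apply_mnar_censoring(m, censor_location = 22,
                                              censor_scale = 1, seed = 7))

  # hard-threshold mode censors exactly below the location
  hard <- apply_mnar_censoring(m, censor_location = 22, censor_scale = 1,
                               mode = "threshold")
  expect_identical(is.na(hard), m < 22)
})

test_that("calibrated censoring hits the target missing fraction", {
  cfg <- generator_config(n_proteins = 3000, de_fraction = 0, seed = 21,
                          missing_target_fraction = 0.15)
  sim <- simulate_proteomics(cfg)
  frac <- mean(is.na(sim$matrix))
  expect_lt(abs(frac - 0.15), 0.01)
})

test_that("proteinGroups tables round-trip through write/read", {
  d <- study_design()
  fx <- ten_protein_fixture(d)
  tab <- assemble_protein_groups(fx$annotations, fx$log2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(tab, path)
  expect_equal(length(readLines(path)), 11)  # header + 10 rows

  pg <- read_protein_groups(path, d)
  expect_equal(pg$records$protein_id, fx$annotations$protein_id)
  expect_equal(pg$records$is_reverse, fx$annotations$is_reverse)
  expect_equal(pg$records$unique_peptides, fx$annotations$unique_peptides)
  expect_equal(is.na(pg$lfq), is.na(fx$log2), ignore_attr = TRUE)
  expect_equal(log2(pg$lfq), fx$log2, tolerance = 1e-10)

  empty <- tab[0, , drop = FALSE]
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(empty, path2)
  expect_equal(length(readLines(path2)), 1)
  expect_equal(nrow(read_protein_groups(path2, d)$records), 0)
})

test_that("simulate_proteomics is deterministic end to end", {
  cfg <- generator_config(n_proteins = 40, seed = 17, contaminant_count = 2,
                          reverse_count = 1)
  s1 <- simulate_proteomics(cfg)
  s2 <- simulate_proteomics(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$matrix, s2$matrix)
})
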