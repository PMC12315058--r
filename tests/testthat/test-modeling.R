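# LAD fitting, error statistics, XTB correction, planarity partition,
# R_opt scan, per-formula transferability, and table/fit serialization.

test_that("isomerization_energies references the group minimum", {
  expect_equal(isomerization_energies(c(10, 12, 15)), c(0, 2, 5))
  expect_equal(isomerization_energies(7), 0)
  tied <- isomerization_energies(c(3, 5, 3))
  expect_equal(sum(tied == 0), 2)
  expect_true(all(tied >= 0))
  expect_error(isomerization_energies(numeric(0)), "empty")
})

test_that("error_stats reproduces hand arithmetic and symmetry", {
  st <- error_stats(c(2, 0), c(1, 2))      # deviations 1, -2
  expect_equal(st$mad, 1.5)
  expect_equal(st$msd, -0.5)
  expect_equal(st$rmsd, sqrt(2.5))
  expect_equal(st$maxd, 2)
  expect_equal(st$n, 2)
  z <- error_stats(1:5, 1:5)
  expect_equal(unlist(z[c("mad", "rmsd", "msd", "maxd")]),
               c(mad = 0, rmsd = 0, msd = 0, maxd = 0))
  set.seed(2)
  p <- rnorm(40); r <- rnorm(40)
  perm <- sample(40)
  expect_equal(unclass(error_stats(p, r))[1:4],
               unclass(error_stats(p[perm], r[perm]))[1:4])
  expect_error(error_stats(1:3, 1:4), "lengths differ")
})

test_that("error-statistic ordering maxd >= rmsd >= mad >= |msd| holds", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    st <- error_stats(rnorm(n, sd = runif(1, 0.1, 10)), rnorm(n))
    expect_gte(st$maxd, st$rmsd - 1e-12)
    expect_gte(st$rmsd, st$mad - 1e-12)
    expect_gte(st$mad, abs(st$msd) - 1e-12)
  }
})

test_that("fit_lad recovers noiseless relationships exactly", {
  set.seed(4)
  x <- runif(30, 0, 10)
  f1 <- fit_lad(cbind(x = x), 2 + 3 * x)
  expect_equal(f1$intercept, 2, tolerance = 1e-8)
  expect_equal(unname(f1$coefficients), 3, tolerance = 1e-8)
  expect_equal(f1$training_stats$mad, 0, tolerance = 1e-8)

  X <- cbind(a = runif(40), b = runif(40, -5, 5))
  f2 <- fit_lad(X, 1.5 - 2 * X[, "a"] + 0.25 * X[, "b"])
  expect_equal(unname(c(f2$intercept, f2$coefficients)),
               c(1.5, -2, 0.25), tolerance = 1e-8)
})

test_that("fit_lad matches the exhaustive grid-search oracle", {
  set.seed(12)
  x <- runif(20, 0, 4)
  y <- 1 + 0.8 * x + rcauchy(20, 0, 0.15)   # heavy-tailed residuals
  fit <- fit_lad(cbind(x = x), y)
  gr <- oracle_lad_grid1(x, y, seq(0, 2, by = 0.01),
                         seq(0, 1.6, by = 0.01))
  expect_lte(fit$training_stats$mad, gr$mad + 1e-12)
  expect_lt(abs(fit$intercept - gr$a0), 0.011)
  expect_lt(abs(unname(fit$coefficients) - gr$a1), 0.011)

  X <- cbind(u = runif(25, 0, 2), v = runif(25, 0, 2))
  y2 <- 0.5 + X[, 1] - 0.6 * X[, 2] + rnorm(25, 0, 0.2)
  fit2 <- fit_lad(X, y2)
  gr2 <- oracle_lad_grid2(X, y2, seq(0, 1, by = 0.02),
                          seq(0.5, 1.5, by = 0.02),
                          seq(-1.1, -0.1, by = 0.02))
  expect_lte(fit2$training_stats$mad, gr2$mad + 1e-12)
  # LAD objectives are piecewise linear and can be flat near the optimum:
  # the exact vertex may sit up to ~2 grid steps from the grid argmin
  expect_lt(max(abs(c(fit2$intercept, fit2$coefficients) - gr2$coef)), 0.041)
})

test_that("fit_lad handles weights, rank deficiency and degenerate sizes", {
  set.seed(5)
  x <- runif(30)
  y <- 1 + x
  y[1:5] <- y[1:5] + 10           # outliers
  w <- rep(1, 30); w[1:5] <- 0    # zero-weighted outliers are ignored
  fw <- fit_lad(cbind(x = x), y, weights = w)
  expect_equal(unname(c(fw$intercept, fw$coefficients)), c(1, 1),
               tolerance = 1e-8)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_lad(X, y), "collinear.*b")
  expect_error(fit_lad(cbind(x = 1:2), 1:2 * 1.0), NA) # n = p is rejected?
  expect_error(fit_lad(cbind(x = 1), 1), "more observations")
})

test_that("intercept-only LAD is the weighted median baseline", {
  set.seed(8)
  y <- rexp(31)
  f0 <- fit_lad(matrix(numeric(0), 31, 0), y)
  expect_equal(f0$intercept, median(y), tolerance = 1e-10)
  # training MAD never exceeds the intercept-only MAD (nested monotonicity)
  for (i in 1:5) {
    X <- cbind(a = rnorm(31), b = rnorm(31))
    yy <- rnorm(31)
    m0 <- fit_lad(matrix(numeric(0), 31, 0), yy)$training_stats$mad
    m1 <- fit_lad(X[, 1, drop = FALSE], yy)$training_stats$mad
    m2 <- fit_lad(X, yy)$training_stats$mad
    expect_lte(m1, m0 + 1e-9)
    expect_lte(m2, m1 + 1e-9)
  }
})

test_that("correct_xtb recovers identity, scaling and an injected line", {
  e <- c(0.5, 2, 4, 7, 11)
  id <- correct_xtb(e, e)
  expect_equal(id$intercept, 0, tolerance = 1e-9)
  expect_equal(unname(id$coefficients), 1, tolerance = 1e-9)
  half <- correct_xtb(0.5 * e, e)
  expect_equal(unname(half$coefficients), 2, tolerance = 1e-9)
  # systematic underestimation: e_xtb = 0.7 e_ref - 4 (+ tiny noise)
  set.seed(3)
  e_ref <- runif(60, 0, 40)
  e_xtb <- -4 + 0.7 * e_ref + rnorm(60, 0, 1e-6)
  cx <- correct_xtb(e_xtb, e_ref)
  expect_equal(unname(cx$coefficients), 1 / 0.7, tolerance = 1e-4)
  expect_equal(cx$intercept, 4 / 0.7, tolerance = 1e-3)
  expect_equal(cx$corrected, e_ref, tolerance = 1e-3)
  # least-squares flag
  ls <- correct_xtb(e_xtb, e_ref, objective = "ls")
  expect_equal(unname(ls$coefficients), 1 / 0.7, tolerance = 1e-4)
})

test_that("planarity_partition is exhaustive, disjoint, boundary-inclusive", {
  tb <- data.frame(id = 1:3, delta_z = c(0.0, 1.0, 1.01))
  pp <- planarity_partition(tb)
  expect_equal(pp$planar$delta_z, c(0.0, 1.0))
  expect_equal(pp$nonplanar$delta_z, 1.01)
  all_planar <- planarity_partition(data.frame(delta_z = c(0.1, 0.9)))
  expect_equal(nrow(all_planar$nonplanar), 0)
  zero <- planarity_partition(tb, threshold = 0)
  expect_equal(zero$planar$delta_z, 0.0)
  expect_error(planarity_partition(data.frame(x = 1)), "delta_z")
})

test_that("ropt_scan recovers an injected optimal bond length", {
  set.seed(21)
  n <- 120
  ring_lengths <- lapply(seq_len(n), function(i)
    lapply(seq_len(sample(2:4, 1)), function(r) runif(6, 1.33, 1.47)))
  r_star <- 1.43
  h_star <- vapply(ring_lengths, homa_from_lengths, 0, r_opt = r_star)
  y <- 5 - 30 * h_star
  grid <- seq(1.35, 1.50, by = 0.01)
  scan <- ropt_scan(y, ring_lengths, grid)
  expect_equal(attr(scan, "best_r_opt"), r_star, tolerance = 0.011)
  expect_equal(nrow(scan), length(grid))
  # determinism and one-point consistency with a direct fit
  scan2 <- ropt_scan(y, ring_lengths, grid)
  expect_identical(scan$mad, scan2$mad)
  one <- ropt_scan(y, ring_lengths, 1.388)
  h0 <- vapply(ring_lengths, homa_from_lengths, 0, r_opt = 1.388)
  direct <- fit_lad(cbind(homa = h0), y)
  expect_equal(one$mad, direct$training_stats$mad, tolerance = 1e-10)
  expect_error(ropt_scan(y, ring_lengths, numeric(0)), "empty")
  expect_error(ropt_scan(y, ring_lengths, 6), "\\(0, 5\\]")
})

test_that("formula parsing and series labeling follow C(16+4n)H(10+2n)", {
  expect_equal(parse_formula("C44H24"), c(C = 44L, H = 24L))
  expect_true(all(in_series(c("C36H20", "C40H22", "C44H24", "C16H10"))))
  expect_false(any(in_series(c("C38H20", "C40H20", "C42H22"))))
  expect_error(parse_formula("C6H6O"), "parse")
})

test_that("per_formula_fit recovers per-group laws and series spread", {
  set.seed(31)
  mk <- function(f, a0) {
    # pin the group minimum at x = -10 so every group shares the same
    # dE_iso law (intercept 3 after min-referencing)
    x <- c(-10, runif(29, 0, 100))
    data.frame(formula = f, x = x, e_ref = a0 + 0.3 * x)
  }
  # identical relationships in every group -> identical coefficients
  tb <- rbind(mk("C36H20", 5), mk("C40H22", 5), mk("C44H24", 5))
  pf <- per_formula_fit(tb, "x")
  slopes <- vapply(pf$fits, function(f) unname(f$coefficients), 0)
  expect_equal(unname(slopes), rep(0.3, 3), tolerance = 1e-8)
  ints <- vapply(pf$fits, function(f) f$intercept, 0)
  expect_equal(unname(ints), rep(3, 3), tolerance = 1e-8)
  expect_equal(pf$in_series,
               c(C36H20 = TRUE, C40H22 = TRUE, C44H24 = TRUE))
  expect_equal(pf$series_summary$max_pct_deviation, c(0, 0),
               tolerance = 1e-6)
  # injected per-group intercept shifts are recovered group by group
  tb2 <- rbind(mk("C36H20", 2), mk("C38H20", 9), mk("C44H24", 4))
  pf2 <- per_formula_fit(tb2, "x")
  # intercepts are relative to each group's own minimum-energy isomer
  for (f in names(pf2$fits)) {
    idx <- tb2$formula == f
    expected_int <- unique(tb2$e_ref[idx] - 0.3 * tb2$x[idx]) -
      min(tb2$e_ref[idx])
    expect_equal(pf2$fits[[f]]$intercept, expected_int[1], tolerance = 1e-7)
  }
  expect_false(pf2$in_series[["C38H20"]])
  expect_warning(
    per_formula_fit(rbind(mk("C36H20", 1), mk("C40H22", 1)[1:2, ]), "x"),
    "skipped")
})

test_that("fit_isomer_table pools per-formula references and can restrict", {
  combo <- c("sum_dihedral", "homa", "theta_rmsd")
  tb <- synth_isomer_table(40, noise_scale = 0, seed = 6)
  # single-group training: dE_iso is exactly linear, slopes recover exactly
  ft <- fit_isomer_table(tb, combo, train_formula = "C36H20")
  expect_equal(unname(ft$coefficients), c(0.0207, -339.00, 16.44),
               tolerance = 1e-6)
  # pooled fit is exact when the groups share the same dE_iso law: use two
  # groups with identical descriptor blocks (hence identical minima)
  one <- synth_isomer_table(40, formulas = "C36H20", noise_scale = 0,
                            seed = 7)
  two <- one
  two$formula <- "C44H24"
  fit <- fit_isomer_table(rbind(one, two), combo)
  expect_equal(unname(fit$coefficients), c(0.0207, -339.00, 16.44),
               tolerance = 1e-6)
  expect_error(fit_isomer_table(tb, c("sum_dihedral", "nope")), "nope")
  expect_error(fit_isomer_table(tb, combo, train_formula = "C99H99"),
               "no rows")
})

test_that("isomer tables and fits round-trip through CSV and JSON", {
  tb <- synth_isomer_table(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_isomer_table(tb, path)
  back <- read_isomer_table(path)
  expect_equal(back$e_ref, tb$e_ref, tolerance = 1e-12)
  # column mapping for foreign exports
  foreign <- tb
  names(foreign)[names(foreign) == "e_ref"] <- "E_iso_ref(kcal/mol)"
  names(foreign)[names(foreign) == "sum_dihedral"] <- "SumDihedral"
  utils::write.csv(foreign, path, row.names = FALSE)
  mapped <- read_isomer_table(path,
                              mapping = c(e_ref = "E_iso_ref(kcal/mol)",
                                          sum_dihedral = "SumDihedral"))
  expect_true(all(c("e_ref", "sum_dihedral") %in% names(mapped)))
  expect_error(read_isomer_table(path, mapping = c(e_ref = "absent")),
               "absent")

  fit <- fit_lad(cbind(x = runif(10)), runif(10))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, jpath)
  back_fit <- read_fit_json(jpath)
  expect_equal(back_fit$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back_fit$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(back_fit$training_stats$mad, fit$training_stats$mad,
               tolerance = 1e-12)
})
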