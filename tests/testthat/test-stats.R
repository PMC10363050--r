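test_that("median/min/max reproduces the printed vascular summary", {
  t1 <- loadStudyTables()$table1
  vas <- t1$m_vas[t1$phase == "local"]
  s <- medianMinMax(vas)
  expect_equal(unname(s$rounded), c(5.5, 1.0, 14.0))
  expect_equal(medianMinMax(3.2), list(median = 3.2, min = 3.2, max = 3.2,
                                       rounded = c(median = 3.2, min = 3.2,
                                                   max = 3.2)))
  expect_error(medianMinMax(numeric(0)), "empty")
})

test_that("even-length medians equal the midpoint of the central pair", {
  set.seed(41)
  for (i in 1:25) {
    x <- round(runif(2 * sample(2:8, 1), 0, 20), 1)
    s <- sort(x)
    expect_equal(medianMinMax(x)$median,
                 (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2)
    # permutation invariance
    expect_equal(medianMinMax(sample(x))$median, medianMinMax(x)$median)
  }
})

test_that("median is monotone in any single element", {
  set.seed(42)
  x <- runif(9, 0, 10)
  m0 <- medianMinMax(x)$median
  for (j in seq_along(x)) {
    y <- x
    y[j] <- y[j] + 3
    expect_gte(medianMinMax(y)$median, m0)
  }
})

test_that("half-up decimal rounding matches the clinical arithmetic", {
  expect_equal(roundHalfUp1(0.25), 0.3)
  expect_equal(roundHalfUp1(4.85), 4.9)
  expect_equal(roundHalfUp1(-0.25), -0.3)
  expect_equal(roundHalfUp1(1.64), 1.6)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  ident <- mannWhitneyU(c(2, 4, 9, 4), c(2, 4, 9, 4))
  expect_equal(ident$p, 1.0)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    a <- round(runif(n, 0, 6), 1)
    b <- round(runif(m, 0, 6), 1)
    got <- mannWhitneyU(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p, enumMWOracle(a, b), tolerance = 1e-12)
    # symmetry of the two-sided p
    expect_equal(mannWhitneyU(b, a)$p, got$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact p agrees with wilcox.test for untied data", {
  set.seed(78)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(5, 0.8)
    expect_equal(mannWhitneyU(a, b)$p,
                 suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-9)
  }
})

test_that("the normal approximation is sane for larger samples", {
  set.seed(79)
  a <- rnorm(30); b <- rnorm(30)
  r <- mannWhitneyU(a, b)
  expect_equal(r$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE,
                                      exact = FALSE)$p.value)
  expect_equal(r$p, ref, tolerance = 1e-6)
  expect_equal(mannWhitneyU(a, a)$p, 1.0)
})

test_that("ICC(A,1) equals 1 under exact rater agreement", {
  x <- cbind(c(1, 5, 9, 2, 7), c(1, 5, 9, 2, 7))
  expect_equal(iccAgreementSingle(x)$icc, 1.0)
  expect_error(iccAgreementSingle(cbind(c(2, 2, 2), c(2, 2, 2))), "variance")
  expect_error(iccAgreementSingle(x[1:2, ]), "three")
})

test_that("ICC reproduces the printed vascular inter-observer agreement", {
  t2 <- loadStudyTables()$table2
  r <- iccAgreementSingle(t2[, c("vas_phys1", "vas_phys2")])
  expect_equal(round(r$icc, 2), 0.98)
  expect_equal(r$band, "excellent")
})

test_that("ICC is invariant to a common additive shift", {
  set.seed(15)
  x <- cbind(rnorm(12, 10, 3), rnorm(12, 10, 3))
  expect_equal(iccAgreementSingle(x + 100)$icc, iccAgreementSingle(x)$icc,
               tolerance = 1e-9)
})

test_that("ICC recovers the variance-component ratio on simulated tables", {
  sim <- function(n, seed) {
    set.seed(seed)
    subj <- rnorm(n, 0, 3)           # subject sd 3 -> variance 9
    cbind(subj + rnorm(n), subj + rnorm(n))  # error variance 1
  }
  # expected ICC = 9 / (9 + 1); bias vanishes as n grows
  errs <- vapply(c(50, 200, 1000), function(n)
    abs(iccAgreementSingle(sim(n, n))$icc - 0.9), numeric(1))
  expect_lt(errs[2], 0.03)
  expect_lt(errs[3], 0.02)
  expect_true(all(errs < 0.08))
})

test_that("median differences reproduce the printed comparison", {
  tabs <- loadStudyTables()
  t1 <- tabs$table1; t2 <- tabs$table2
  expect_equal(medianDifference(t1$m_bone[t1$phase == "local"], t2$bone_total),
               0.1)
  expect_equal(medianDifference(t1$m_vas[t1$phase == "local"], t2$vas_total),
               0.6)
  expect_equal(medianDifference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(medianDifference(c(1, 2), c(2, 3), paired = TRUE), 1)
  expect_error(medianDifference(numeric(0), 1), "non-empty")
})

test_that("the fixture loader surfaces, and does not repair, inconsistencies", {
  tabs <- loadStudyTables()
  expect_equal(length(unique(tabs$table1$patient)), 10)
  expect_equal(nrow(tabs$table2), 10)
  expect_true(any(grepl("patient 4 bone", tabs$flags)))
  expect_false(any(grepl("vas", tabs$flags)))
  # the printed (inconsistent) cell is preserved
  expect_equal(tabs$table2$bone_total[tabs$table2$patient == 4], 0.1)
})

test_that("summary reproduction flags a perturbed fixture", {
  dir <- tempdir()
  src <- system.file("extdata", package = "autofuse")
  file.copy(file.path(src, "table1_automated.csv"), dir, overwrite = TRUE)
  file.copy(file.path(src, "table2_manual.csv"), dir, overwrite = TRUE)
  t1 <- read.csv(file.path(dir, "table1_automated.csv"))
  # perturb a central value by +5 mm so the median itself moves
  t1$m_vas[t1$phase == "local" & t1$patient == 9] <- 11  # was 6.0
  write.csv(t1, file.path(dir, "table1_automated.csv"), row.names = FALSE)
  rep <- reproduceSummaries(loadStudyTables(dir))
  row <- rep[rep$summary == "table1 automated vascular median (local)", ]
  expect_false(row$match)
  expect_false(attr(rep, "pass"))

  # an empty fixture directory fails to load
  empty <- file.path(tempdir(), "emptyfix")
  dir.create(empty, showWarnings = FALSE)
  write.csv(data.frame(), file.path(empty, "table1_automated.csv"),
            row.names = FALSE)
  write.csv(data.frame(), file.path(empty, "table2_manual.csv"),
            row.names = FALSE)
  expect_error(loadStudyTables(empty))
})
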