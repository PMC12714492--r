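# Odds ratios, Z-tests, homogeneity and the rescue fixture.

test_that("odds ratio is the cross-product ratio with inversion symmetry", {
  expect_equal(odds_ratio(two_by_two(13, 3, 208, 183)), 3.8125)
  expect_equal(round(odds_ratio(two_by_two(8, 2, 63, 173)), 3), 10.984)
  expect_equal(odds_ratio(two_by_two(1, 1, 1, 1)), 1)
  # swapping exposure inverts the odds ratio exactly
  for (ce in list(c(13, 3, 208, 183), c(5, 1, 145, 10), c(7, 2, 9, 4))) {
    t1 <- two_by_two(ce[1], ce[2], ce[3], ce[4])
    t2 <- two_by_two(ce[2], ce[1], ce[4], ce[3])
    expect_equal(odds_ratio(t1) * odds_ratio(t2), 1, tolerance = 1e-12)
  }
  expect_error(odds_ratio(two_by_two(0, 1, 2, 3)), "continuity")
  expect_equal(odds_ratio(two_by_two(0, 1, 2, 3), continuity = TRUE),
               (0.5 * 3.5) / (1.5 * 2.5))
  expect_error(two_by_two(-1, 1, 1, 1), "non-negative")
  expect_error(two_by_two(0, 0, 0, 0), "empty")
})

test_that("log odds-ratio Z-test reproduces the published triplets", {
  cases <- list(list(ce = c(13, 3, 208, 183), lor = 1.338, z = 2.064,
                     p = 0.020),
                list(ce = c(11, 5, 197, 194), lor = 0.773, z = 1.409,
                     p = 0.079),
                list(ce = c(10, 6, 236, 155), lor = 0.0904, z = 0.172,
                     p = 0.432))
  for (cs in cases) {
    ht <- log_or_test(do.call(two_by_two, as.list(cs$ce)), "greater")
    expect_equal(unname(ht$estimate["log odds ratio"]), cs$lor,
                 tolerance = 5e-3)
    expect_equal(unname(ht$statistic), cs$z, tolerance = 5e-3)
    expect_equal(ht$p.value, cs$p, tolerance = 5e-2)
    # SE is the standard 1/cell sum
    expect_equal(unname(ht$estimate["SE"]), sqrt(sum(1 / cs$ce)),
                 tolerance = 1e-12)
  }
})

test_that("Z is antisymmetric and one-sided p-values are complementary", {
  set.seed(42)
  for (i in 1:25) {
    ce <- stats::rpois(4, 30) + 1
    t1 <- two_by_two(ce[1], ce[2], ce[3], ce[4])
    t2 <- two_by_two(ce[2], ce[1], ce[4], ce[3])
    z1 <- unname(log_or_test(t1)$statistic)
    z2 <- unname(log_or_test(t2)$statistic)
    expect_equal(z1, -z2, tolerance = 1e-12)
    pg <- log_or_test(t1, "greater")$p.value
    pl <- log_or_test(t1, "less")$p.value
    expect_equal(pg + pl, 1, tolerance = 1e-12)
    p2 <- log_or_test(t1, "two.sided")$p.value
    expect_equal(p2, 2 * min(pg, pl), tolerance = 1e-12)
  }
})

test_that("Woolf homogeneity matches its direct formula and invariances", {
  s1 <- two_by_two(5, 1, 145, 10)
  s2 <- two_by_two(8, 2, 63, 173)
  ht <- or_homogeneity_test(list(s1, s2))
  # independent evaluation of the inverse-variance weighted statistic
  lor <- c(log((5 * 10) / (1 * 145)), log((8 * 173) / (2 * 63)))
  w <- c(1 / (1 / 5 + 1 / 1 + 1 / 145 + 1 / 10),
         1 / (1 / 8 + 1 / 2 + 1 / 63 + 1 / 173))
  pooled <- sum(w * lor) / sum(w)
  chi2 <- sum(w * (lor - pooled)^2)
  expect_equal(unname(ht$statistic), chi2, tolerance = 1e-12)
  expect_equal(unname(ht$parameter), 1)
  expect_equal(ht$p.value, stats::pchisq(chi2, 1, lower.tail = FALSE))

  # order invariance and zero on identical strata
  ht_rev <- or_homogeneity_test(list(s2, s1))
  expect_equal(unname(ht_rev$statistic), unname(ht$statistic),
               tolerance = 1e-12)
  same <- or_homogeneity_test(list(s1, s1, s1))
  expect_equal(unname(same$statistic), 0, tolerance = 1e-12)
  expect_equal(unname(same$parameter), 2)
  # equal odds ratios (not equal tables) also give zero
  eq <- or_homogeneity_test(list(two_by_two(2, 1, 4, 8),
                                 two_by_two(8, 2, 2, 2)))
  expect_equal(unname(eq$statistic), 0, tolerance = 1e-12)
  expect_error(or_homogeneity_test(list(s1)), "at least 2")
})

test_that("Breslow-Day agrees with Woolf direction and is exact on nulls", {
  s1 <- two_by_two(5, 1, 145, 10)
  s2 <- two_by_two(8, 2, 63, 173)
  bd <- or_homogeneity_test(list(s1, s2), method = "breslow-day")
  expect_gt(unname(bd$statistic), stats::qchisq(0.95, 1))  # heterogeneous
  expect_lt(bd$p.value, 0.05)
  # strata sharing a common OR: statistic near zero
  null <- or_homogeneity_test(list(two_by_two(10, 5, 20, 20),
                                   two_by_two(30, 15, 12, 12)),
                              method = "breslow-day")
  expect_lt(unname(null$statistic), 1e-10)
})

test_that("tables are built from presence per cell, not event counts", {
  exposure <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  events <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  tb <- build_table(exposure, events)
  expect_equal(unname(tb[1, ]), c(2, 1))   # a, b
  expect_equal(unname(tb[2, ]), c(1, 1))   # c, d
  expect_equal(sum(tb), length(exposure))
  # no events at all
  t0 <- build_table(exposure, rep(FALSE, 5))
  expect_equal(unname(t0[1, ]), c(0, 0))
})

test_that("classification is strictly greater-than the thresholds", {
  map <- data.frame(subgrid_id = c("a", "b", "c"),
                    p_tiger_use = c(0.54, 0.541, 0.2),
                    p_prey_use = c(0.80, 0.9, 0.81))
  pop <- data.frame(subgrid_id = c("a", "b", "c"),
                    density = c(141, 142, 500))
  cl <- classify_subgrids(map, pop)
  expect_equal(cl$tiger_high, c(FALSE, TRUE, FALSE))  # at threshold = low
  expect_equal(cl$prey_high, c(FALSE, TRUE, TRUE))
  expect_equal(cl$pop_high, c(FALSE, TRUE, TRUE))
  # buffer restriction drops cells from the counts
  clb <- classify_subgrids(map, pop, buffer = c("a", "b"))
  expect_equal(nrow(clb), 2)
  # mismatched cell sets are reported
  expect_error(classify_subgrids(map, pop[-1, ], ), "different cells")
  # thresholds recomputable from the data at hand
  clr <- classify_subgrids(map, pop, recompute = TRUE)
  expect_equal(clr$pop_high, pop$density > mean(pop$density))
})

test_that("marginal association collapses the event dimension", {
  s1 <- two_by_two(5, 1, 145, 10)     # low population stratum
  s2 <- two_by_two(8, 2, 63, 173)     # high population stratum
  m <- marginal_association(list(s1, s2))
  expect_equal(unname(.subset(m$table, c(1, 3, 2, 4))), c(150, 71, 11, 175))
  expect_equal(round(m$or, 2), 33.61)
  # identical margins give OR 1
  same <- marginal_association(list(two_by_two(3, 2, 7, 8),
                                    two_by_two(5, 4, 5, 6)))
  expect_equal(same$or, 1)
  expect_error(marginal_association(list(s1)), "exactly 2")
})

test_that("naive occupancy is the detected fraction of surveyed units", {
  expect_equal(round(naive_occupancy(36, 57), 2), 0.63)
  expect_equal(naive_occupancy(0, 57), 0)
  expect_equal(naive_occupancy(57, 57), 1)
  expect_error(naive_occupancy(5, 0), "no surveyed")
  expect_error(naive_occupancy(58, 57), "exceed")
})

test_that("the packaged fixture loads into valid tables", {
  ft <- fixture_tables()
  expect_named(ft$overall, c("population", "prey_use", "tiger_use"),
               ignore.order = TRUE)
  expect_equal(sum(ft$overall$prey_use), 407)   # buffer subgrid count
  expect_equal(sum(ft$overall$tiger_use), 407)
  expect_named(ft$prey_by_population,
               c("low_population", "high_population"))
  # strata partition the buffer cells
  expect_equal(sum(ft$prey_by_population$low_population) +
                 sum(ft$prey_by_population$high_population), 407)
  expect_equal(sum(ft$age_sex[, -1]), 32)       # rescued animals
})
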