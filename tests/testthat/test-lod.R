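test_that("pooled ladder is the descending union of all series", {
  grids <- load_fixture_table1()
  expect_equal(pooled_ladder(grids$BP),
               c(15, 12.5, 10, 7.5, 6.25, 5, 3.75, 3.13, 2.5, 1.88, 1.56,
                 1.25, 0.94, 0.78, 0.63))
  one <- dilution_grid("X", data.frame(series = 1, conc = c(10, 5, 2.5),
                                       run = 1, positive_wells = 5, n_wells = 5))
  expect_equal(pooled_ladder(one), c(10, 5, 2.5))
  dup <- dilution_grid("X", data.frame(series = c(1, 2), conc = c(5, 5),
                                       run = 1, positive_wells = 5, n_wells = 5))
  expect_equal(pooled_ladder(dup), 5)
})

test_that("fixture grids reproduce the published LoD row", {
  grids <- load_fixture_table1()
  bp <- estimate_lod(grids$BP)
  expect_equal(bp$bound, "EXACT_STEP")
  expect_equal(bp$lod_cps_per_well, 1.56)
  expect_equal(bp$triggering_conc, 1.25)
  cp <- estimate_lod(grids$CP)
  expect_equal(cp$bound, "EXACT_STEP")
  expect_equal(cp$lod_cps_per_well, 3.75)
  expect_equal(cp$triggering_conc, 3.13)
  for (it in c("MP", "LP")) {
    est <- estimate_lod(grids[[it]])
    expect_equal(est$bound, "BELOW_RANGE")
    expect_equal(est$lod_cps_per_well, 0.63)
    expect_true(is.na(est$triggering_conc))
    expect_match(format(est), "^< 0.63")
  }
})

test_that("an all-negative run at the top concentration is above range", {
  g <- dilution_grid("X", data.frame(series = 1, conc = rep(c(10, 5), each = 2),
                                     run = rep(1:2, 2),
                                     positive_wells = c(0, 5, 3, 2),
                                     n_wells = 5))
  est <- estimate_lod(g)
  expect_equal(est$bound, "ABOVE_RANGE")
  expect_equal(est$triggering_conc, 10)
})

test_that("within-series mode steps inside the triggering series", {
  # CP: triggering run at 3.13 lies in series 2 (..., 6.25, 3.13, ...), so
  # the within-series step lands on 6.25 instead of the pooled 3.75.
  grids <- load_fixture_table1()
  cp_within <- estimate_lod(grids$CP, mode = "within-series")
  expect_equal(cp_within$lod_cps_per_well, 6.25)
  bp_within <- estimate_lod(grids$BP, mode = "within-series")
  expect_equal(bp_within$lod_cps_per_well, 2.5)  # series 3: 2.50 above 1.25
})

test_that("estimate_lod agrees with the brute-force oracle on random grids", {
  set.seed(2024)
  for (i in 1:200) {
    g <- random_grid(n_conc = sample(3:7, 1), runs = sample(2:4, 1))
    want <- lod_oracle(g)
    got <- estimate_lod(g)
    expect_equal(got$bound, want$bound)
    if (want$bound != "ABOVE_RANGE")
      expect_equal(got$lod_cps_per_well, want$lod)
  }
})

test_that("no all-negative run exists above an EXACT_STEP LoD", {
  set.seed(7)
  for (i in 1:50) {
    g <- random_grid()
    est <- estimate_lod(g)
    if (est$bound == "EXACT_STEP") {
      above <- g[g$conc > est$triggering_conc, ]
      expect_true(all(above$positive_wells > 0L))
      expect_gt(est$lod_cps_per_well, est$triggering_conc)
      expect_true(est$lod_cps_per_well %in% pooled_ladder(g))
    }
  }
})

test_that("removing an all-negative run never raises the LoD", {
  set.seed(99)
  tried <- 0L
  while (tried < 50L) {
    g <- random_grid(n_conc = 5, runs = 3)
    zeros <- which(g$positive_wells == 0L)
    if (length(zeros) == 0L) next
    tried <- tried + 1L
    before <- lod_rank(estimate_lod(g))
    drop <- g[-zeros[1L], , drop = FALSE]
    # keep every concentration represented so the ladder is unchanged
    if (!setequal(unique(drop$conc), unique(g$conc))) next
    after <- lod_rank(estimate_lod(dilution_grid("X", drop)))
    expect_lte(after, before)
  }
})

test_that("hit-rate summary pools wells across series and runs", {
  grids <- load_fixture_table1()
  hr <- hit_rate_summary(grids$BP)
  expect_equal(hr$conc, pooled_ladder(grids$BP))
  top <- hr[hr$conc == 15, ]
  expect_equal(top$total_wells, 25L)  # one series x five runs x five wells
  expect_equal(top$hit_rate, 1.0)
  expect_true(all(hr$hit_rate >= 0 & hr$hit_rate <= 1))

  g <- dilution_grid("X", data.frame(series = 1, conc = 5, run = 1:2,
                                     positive_wells = c(0, 5), n_wells = 5))
  expect_equal(hit_rate_summary(g)$hit_rate, 0.5)
})

test_that("grid validation rejects malformed records", {
  expect_error(dilution_grid("X", data.frame(series = 1, conc = 0, run = 1,
                                             positive_wells = 1, n_wells = 5)),
               "> 0")
  expect_error(dilution_grid("X", data.frame(series = 1, conc = 5, run = 1,
                                             positive_wells = 6, n_wells = 5)),
               "positive_wells")
  expect_error(dilution_grid("X", data.frame(series = 1, conc = c(5, 5),
                                             run = c(1, 1),
                                             positive_wells = 2, n_wells = 5)),
               "duplicated")
})

test_that("detection-efficiency fit recovers the generating efficiency", {
  ladder <- pooled_ladder(load_fixture_table1()$BP)
  set.seed(31)
  e_true <- 1.0
  rec <- expand.grid(conc = ladder, run = 1:50)
  rec$series <- 1L
  rec$n_wells <- 5L
  rec$positive_wells <- stats::rbinom(nrow(rec), 5, 1 - exp(-e_true * rec$conc))
  fit <- fit_detection_efficiency(dilution_grid("X", rec))
  expect_lt(abs(fit$efficiency - e_true) / e_true, 0.10)
  # closed form: e = 1 gives lod95 = -ln(0.05) ~ 2.996 cps/well
  expect_equal(-log(0.05), 2.9957, tolerance = 1e-4)
  expect_equal(fit$lod95, -log(0.05) / fit$efficiency)
})

test_that("efficiency MLE matches an independent cloglog GLM fit", {
  g <- load_fixture_table1()$BP
  fit <- fit_detection_efficiency(g)
  # p = 1 - exp(-e*lambda) is binomial with cloglog link and offset log(lambda)
  glm_fit <- stats::glm(cbind(positive_wells, n_wells - positive_wells) ~ 1 +
                          offset(log(conc)),
                        family = stats::binomial("cloglog"),
                        data = as.data.frame(g))
  expect_equal(fit$efficiency, exp(unname(stats::coef(glm_fit)[1])),
               tolerance = 1e-4)
})

test_that("degenerate grids are non-identifiable", {
  allpos <- dilution_grid("X", data.frame(series = 1, conc = c(10, 5), run = 1,
                                          positive_wells = 5, n_wells = 5))
  expect_error(fit_detection_efficiency(allpos), "non-identifiable")
  allneg <- dilution_grid("X", data.frame(series = 1, conc = c(10, 5), run = 1,
                                          positive_wells = 0, n_wells = 5))
  expect_error(fit_detection_efficiency(allneg), "non-identifiable")
})
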