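test_that("layout validation enforces the 25-well chip contract", {
  lay <- default_layout()
  expect_length(lay$wells, 25L)
  expect_setequal(names(lay$items), c("BP", "MP", "CP", "LP", "IC"))
  expect_true(all(lengths(lay$items) == 5L))
  expect_equal(lay$cutoffs[["swab"]], 15)
  expect_equal(lay$cutoffs[["sputum"]], 20)

  w <- lay$wells
  expect_error(panel_layout(w[-1]), "25 well addresses")
  expect_error(panel_layout(w, control_item = "XX"), "no wells")
  expect_error(panel_layout(w, cutoffs = c(swab = -1)), "positive")
})

test_that("one positive well makes the item positive; all-negative chips are negative", {
  lay <- panel_layout(default_layout()$wells)  # no control item
  # BP pattern (POS,NEG,NEG,NEG,NEG), everything else negative
  traces <- make_chip_traces(lay, pos_wells = lay$items$BP[1])
  res <- call_panel(traces, lay, "swab")
  expect_equal(res$item_results$BP$status, "POSITIVE")
  expect_equal(res$item_results$BP$positive_well_count, 1L)
  for (it in c("MP", "CP", "LP"))
    expect_equal(res$item_results[[it]]$status, "NEGATIVE")
  expect_false(res$coinfection)
  expect_true(res$run_valid)

  blank <- call_panel(make_chip_traces(lay, character(0)), lay, "swab")
  expect_true(all(vapply(blank$item_results, `[[`, "", "status") == "NEGATIVE"))
  expect_false(blank$coinfection)
  expect_true(blank$run_valid)  # no control item: always valid
})

test_that("co-infection is flagged iff two or more targets fire", {
  lay <- default_layout()
  res <- call_panel(make_chip_traces(lay, c(lay$items$BP, lay$items$MP[1])),
                    lay, "swab")
  expect_true(res$coinfection)
  expect_equal(res$item_results$BP$positive_well_count, 5L)
  expect_equal(res$item_results$MP$positive_well_count, 1L)

  # the control item firing does not count toward co-infection
  res2 <- call_panel(make_chip_traces(lay, c(lay$items$BP[1], lay$items$IC)),
                     lay, "swab")
  expect_false(res2$coinfection)
})

test_that("control validation: run invalid only when nothing amplified", {
  lay <- default_layout()
  # control 3/5, all targets negative -> valid
  r1 <- call_panel(make_chip_traces(lay, lay$items$IC[1:3]), lay, "swab")
  expect_true(r1$run_valid)
  # nothing amplified anywhere -> invalid
  r2 <- call_panel(make_chip_traces(lay, character(0)), lay, "swab")
  expect_false(r2$run_valid)
  # control dead but a target fired -> still valid (default), invalid (strict)
  r3 <- call_panel(make_chip_traces(lay, lay$items$BP[1:2]), lay, "swab")
  expect_true(r3$run_valid)
  expect_equal(r3$item_results$BP$status, "POSITIVE")
  r3s <- call_panel(make_chip_traces(lay, lay$items$BP[1:2]), lay, "swab",
                    strict_control = TRUE)
  expect_false(r3s$run_valid)
  # invalid runs keep their item statuses
  expect_equal(r2$item_results$BP$status, "NEGATIVE")
})

test_that("missing traces and unknown sample types are rejected", {
  lay <- default_layout()
  traces <- make_chip_traces(lay, character(0))
  expect_error(call_panel(traces[-1], lay, "swab"), "incomplete run")
  expect_error(call_panel(traces, lay, "plasma"), "unknown sample_type")
})

test_that("item results are invariant to well relabeling within an item", {
  lay <- default_layout()
  for (wells in list(lay$items$BP[c(2, 4)], lay$items$BP[c(1, 3)])) {
    res <- call_panel(make_chip_traces(lay, wells), lay, "swab")
    expect_equal(res$item_results$BP$status, "POSITIVE")
    expect_equal(res$item_results$BP$positive_well_count, 2L)
  }
})

test_that("raising the cutoff can only turn items positive, never negative", {
  lay <- default_layout()
  # Tt of 17 min: negative for swab (15), positive for sputum (20)
  traces <- make_chip_traces(lay, lay$items$CP[1], tt = 17, duration = 20)
  swab <- call_panel(traces, lay, "swab")
  sputum <- call_panel(traces, lay, "sputum")
  expect_equal(swab$item_results$CP$status, "NEGATIVE")
  expect_equal(sputum$item_results$CP$status, "POSITIVE")
  for (it in names(lay$items)) {
    s1 <- swab$item_results[[it]]$status
    s2 <- sputum$item_results[[it]]$status
    expect_false(s1 == "POSITIVE" && s2 == "NEGATIVE")
  }
})

test_that("panel result export carries the per-well Tt table", {
  lay <- default_layout()
  res <- call_panel(make_chip_traces(lay, lay$items$BP), lay, "swab")
  df <- as.data.frame(res)
  expect_equal(nrow(df), 25L)
  expect_setequal(unique(df$item), names(lay$items))
  expect_equal(sum(df$status == "POSITIVE"), 5L)
  s <- summary(res)
  expect_equal(s$positive_wells[s$item == "BP"], 5L)

  tmp <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_result(res, tmp, tsv_path = tsv)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$items$BP$status, "POSITIVE")
  expect_true(back$run_valid)
  expect_equal(nrow(utils::read.delim(tsv)), 25L)
})

test_that("layout JSON round-trips through read/write", {
  lay <- default_layout()
  tmp <- tempfile(fileext = ".json")
  write_layout(lay, tmp)
  back <- read_layout(tmp)
  expect_equal(back$wells, lay$wells)
  expect_equal(back$control_item, lay$control_item)
  expect_equal(back$cutoffs, lay$cutoffs)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(wells = as.list(lay$wells), cutoffs = list(swab = 15),
                            extra_key = 1), bad, auto_unbox = TRUE)
  expect_error(read_layout(bad), "unknown layout keys")
})
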