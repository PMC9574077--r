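test_that("reading a complete panel returns it intact, in normalized order", {
  df <- tiny_indicator_df()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[sample(nrow(df)), ], f, row.names = FALSE)
  p <- read_panel(f)
  expect_s3_class(p, "indicator_panel")
  expect_equal(nrow(p), 4)
  expect_false(attr(p, "positivized"))
  expect_equal(p$unit, c("A", "A", "B", "B"))
  expect_equal(p$I1[p$unit == "A" & p$year == 2009], 900)
})

test_that("balance and validity violations are rejected with the offending cell named", {
  df <- tiny_indicator_df()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-2, ], f, row.names = FALSE)
  expect_error(read_panel(f), "missing record for unit 'B', year 2009")
  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(read_panel(f), "duplicate record for unit 'A', year 2009")
  bad <- df; bad$M2[3] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_panel(f), "non-positive.*'M2' at unit 'A', year 2010")
  expect_error(as_indicator_panel(df[, -3]), "missing column")
})

test_that("write_panel / read_panel round-trips a synthetic panel to full precision", {
  g <- generate_dea_panel(synthetic_dea_config(n_units = 6, years = 2009:2010,
                                               n_frontier = 2, seed = 42))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(g$panel, f)
  back <- read_panel(f)
  for (cl in c("I1", "M1", "M2", "M3", "F1", "F2", "F3", "F4", "F5")) {
    expect_identical(back[[cl]], g$panel[[cl]])
  }
})

test_that("positivization takes reciprocals of F3-F5 only, once", {
  df <- tiny_indicator_df()
  p <- as_indicator_panel(df)
  q <- positivize_indicators(p)
  expect_true(attr(q, "positivized"))
  expect_equal(q$F4[q$unit == "B" & q$year == 2009], 2.0)  # 1 / 0.5
  expect_equal(1 / 0.0046, 217.391, tolerance = 1e-5)      # magnitude check
  expect_identical(q$I1, p$I1)
  expect_identical(q$F1, p$F1)
  # reciprocal of reciprocal returns the original
  expect_equal(1 / q$F3, p$F3, tolerance = 1e-12)
  expect_error(positivize_indicators(q), "already positivized")
  bad <- df; bad$F5[1] <- 0
  expect_error(as_indicator_panel(bad), "non-positive")
})

test_that("positivization rejects a zero rate explicitly", {
  df <- tiny_indicator_df()
  p <- as_indicator_panel(df)
  # inject the zero after construction to hit the reciprocal guard itself
  p$F5[1] <- 0
  expect_error(positivize_indicators(p), "reciprocal undefined")
})

test_that("descriptive statistics use the sample sd and respect balance", {
  d <- compute_descriptives(c(1, 2, 3))
  expect_equal(d$n, 3)
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$min, 1)
  expect_equal(d$max, 3)
  expect_error(compute_descriptives(numeric(0)), "empty")
  # balance property: grand mean equals the mean of per-unit means
  g <- generate_dea_panel(synthetic_dea_config(n_units = 8, years = 2009:2012,
                                               n_frontier = 2, seed = 9))
  p <- g$panel
  grand <- compute_descriptives(p$I1)$mean
  per_unit <- vapply(split(p$I1, p$unit), mean, numeric(1))
  expect_equal(grand, mean(per_unit), tolerance = 1e-12)
})

test_that("the packaged regional grouping partitions the 31 provinces 11/8/12", {
  rg <- china_regions()
  expect_equal(nrow(rg), 31)
  expect_equal(sort(unique(rg$unit)), sort(china_provinces()))
  expect_equal(as.integer(table(rg$region)[c("eastern", "central", "western")]),
               c(11L, 8L, 12L))
})
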