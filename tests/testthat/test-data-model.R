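test_that("TAC tables parse into per-region curves and survive a round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame_start = c(0, 1, 2), frame_end = c(1, 2, 4),
                   putamen = c(1.25, 7.5, 3.125), cerebellum = c(2, 5, 1))
  write.csv(df, path, row.names = FALSE)
  tacs <- read_tac_table(path, injected_dose = 330, body_weight = 85.4)
  expect_named(tacs, c("putamen", "cerebellum"))
  expect_length(tacs$putamen$activity, 3)
  expect_identical(tacs$cerebellum$activity, c(2, 5, 1))

  out <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(tacs, out)
  back <- read_tac_table(out, injected_dose = 330, body_weight = 85.4)
  expect_equal(back$putamen$activity, tacs$putamen$activity)
  expect_equal(back$putamen$frame_end, tacs$putamen$frame_end)
})

test_that("frame gaps from scan breaks are preserved, row order is immaterial", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame_start = c(0, 45, 120), frame_end = c(45, 90, 150),
                   thalamus = c(3, 2, 1))
  write.csv(df, path, row.names = FALSE)
  tacs <- read_tac_table(path)
  expect_equal(tacs$thalamus$frame_start, c(0, 45, 120))

  shuffled <- df[c(3, 1, 2), ]
  write.csv(shuffled, path, row.names = FALSE)
  expect_equal(read_tac_table(path)$thalamus$activity, c(3, 2, 1))
})

test_that("malformed TAC tables are rejected with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad_order <- data.frame(frame_start = c(0, 2, 4), frame_end = c(2, 1, 6),
                          roi = c(1, 1, 1))
  write.csv(bad_order, path, row.names = FALSE)
  expect_error(read_tac_table(path), "rows: 2")

  overlap <- data.frame(frame_start = c(0, 1, 4), frame_end = c(2, 4, 6),
                        roi = c(1, 1, 1))
  write.csv(overlap, path, row.names = FALSE)
  expect_error(read_tac_table(path), "overlap")

  neg <- data.frame(frame_start = c(0, 2), frame_end = c(2, 4),
                    roi = c(1, -1))
  write.csv(neg, path, row.names = FALSE)
  expect_error(read_tac_table(path), "non-negative")

  nocols <- data.frame(frame_start = c(0, 2), roi = c(1, 1))
  write.csv(nocols, path, row.names = FALSE)
  expect_error(read_tac_table(path), "frame_end")
})

test_that("SUV scaling matches activity * weight / dose and inverts exactly", {
  x <- tac("r", 0, 1, 10, injected_dose = 350, body_weight = 70)
  s <- to_suv(x)
  expect_equal(s$activity, 2.0)
  expect_identical(s$units, "SUV")

  x0 <- tac("r", 0, 1, 0, injected_dose = 350, body_weight = 70)
  expect_equal(to_suv(x0)$activity, 0)

  y <- tac("r", c(0, 1, 2), c(1, 2, 3), c(3.7, 11.1, 0.3),
           injected_dose = 326, body_weight = 81.2)
  expect_equal(from_suv(to_suv(y))$activity, y$activity)

  expect_error(to_suv(tac("r", 0, 1, 10)), "injected_dose")
})

test_that("parent fraction model starts at 1, decays monotonically to its plateau", {
  pf <- parent_fraction_model()
  tt <- seq(0, 210, by = 1)
  v <- predict_parent_fraction(pf, tt)
  expect_equal(v[1], 1)
  expect_true(all(diff(v) <= 0))
  expect_equal(predict_parent_fraction(pf, 60), 0.27, tolerance = 1e-10)
  expect_equal(predict_parent_fraction(pf, 1e5), 0.25, tolerance = 1e-6)
})

test_that("metabolite correction is the pointwise parent-fraction scaling", {
  tt <- seq(0, 120, by = 5)
  total <- 50 * exp(-0.05 * tt)

  ident <- metabolite_correct(tt, total, parent_fraction_model(plateau = 1),
                              fp = 0.48)
  expect_equal(ident$conc, total)

  pf <- parent_fraction_model(plateau = 0.25, decay_rate = 0.1)
  late <- metabolite_correct(tt, total, pf, fp = 0.48)
  expect_equal(late$conc[tt >= 90], 0.25 * total[tt >= 90], tolerance = 1e-3)

  zero <- metabolite_correct(tt, total * 0, pf, fp = 0.48)
  expect_true(all(zero$conc == 0))

  expect_error(metabolite_correct(tt, -total, pf, fp = 0.48), "non-negative")
})

test_that("SUV scaling commutes with metabolite correction on plasma-scaled TACs", {
  # both operations are pointwise scalings, so order must not matter
  pf <- parent_fraction_model()
  tt <- seq(0, 90, by = 0.5)
  scale_then_pf <- predict_parent_fraction(pf, tt) * (85.4 / 330) * (20 * exp(-0.1 * tt))
  pf_then_scale <- (85.4 / 330) * (predict_parent_fraction(pf, tt) * 20 * exp(-0.1 * tt))
  expect_equal(scale_then_pf, pf_then_scale)
})

test_that("missing plasma free fraction defaults to 1 with a warning", {
  expect_warning(f <- input_function(c(0, 1), c(0, 5)), "fp = 1")
  expect_equal(f$fp, 1)
})

test_that("the minute/hour unit bridge is exact and self-inverse", {
  expect_equal(minutes_to_hours(90), 1.5)
  expect_equal(hours_to_minutes(minutes_to_hours(c(0, 7, 245))), c(0, 7, 245))
})

test_that("study records enforce dosing metadata on blocking conditions", {
  tc <- tac("r", 0, 1, 1)
  expect_error(study_record("S1", "blocking_1", list(r = tc)), "drug_dose")
  rec <- study_record("S1", "blocking_1", list(r = tc), drug_dose = 600,
                      dose_to_scan_interval = 2)
  expect_s3_class(rec, "study_record")
})
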