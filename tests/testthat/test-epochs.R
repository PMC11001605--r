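# Probe labeling, class-dependent window augmentation and participant
# inclusion rules.

test_that("probe labeling follows the response/confidence rules", {
  expect_equal(label_probe(3, 2), "MW")
  expect_equal(label_probe(1, 3), "nonMW")
  expect_equal(label_probe(2, 2), "nonMW")
  expect_equal(label_probe(3, 1), "excluded")
  expect_equal(label_probe(c(3, 1, 3), c(2, 3, 1)),
               c("MW", "nonMW", "excluded"))
  expect_error(label_probe(4, 2), "response")
  expect_error(label_probe(2, 0), "confidence")
})

test_that("MW probes get 4 dense windows, nonMW 2 coarse windows", {
  fs <- 256
  s <- make_session(matrix(rnorm(2 * 120 * fs), 2), fs)
  s$rejected_intervals <- matrix(numeric(0), ncol = 2)
  p <- make_probe(100, "p1")
  w_mw <- augment_windows(s, p, "MW")
  expect_length(w_mw, 4)
  expect_equal(sapply(w_mw, `[[`, "offset"), c(0, 2.5, 5, 7.5))
  # window k ends at 100 - 2.5 k and spans 10 s -> earliest onset 82.5 s
  expect_equal(ncol(w_mw[[1]]$data), 2560)
  expect_equal(w_mw[[4]]$data,
               s$signal[, (round(82.5 * fs) + 1):(round(92.5 * fs)), drop = FALSE])
  expect_equal(w_mw[[1]]$data,
               s$signal[, (round(90 * fs) + 1):(round(100 * fs)), drop = FALSE])

  w_non <- augment_windows(s, p, "nonMW")
  expect_length(w_non, 2)
  expect_equal(sapply(w_non, `[[`, "offset"), c(0, 5))
  expect_equal(w_non[[2]]$data,
               s$signal[, (round(85 * fs) + 1):(round(95 * fs)), drop = FALSE])
  expect_error(augment_windows(s, p, "excluded"), "label")
})

test_that("windows that leave the block are dropped", {
  fs <- 256
  s <- make_session(matrix(rnorm(2 * 120 * fs), 2), fs)
  s$rejected_intervals <- matrix(numeric(0), ncol = 2)
  p <- make_probe(12, "p_early")
  expect_warning(w <- augment_windows(s, p, "MW"), "dropped")
  # only offsets 0 and 2 s fit: starts at 2 and -0.5 ... => offsets 0 fits,
  # 2.5 fits (start -0.5 < 0 dropped): check all retained windows in bounds
  expect_true(length(w) >= 1)
  for (e in w) expect_gte(12 - e$offset - 10, 0)
})

test_that("evaluation window is the 10 s ending at the probe", {
  fs <- 256
  s <- make_session(matrix(rnorm(1 * 120 * fs), 1), fs)
  s$rejected_intervals <- matrix(numeric(0), ncol = 2)
  w <- test_window(s, make_probe(100, "p1"), "MW")
  expect_equal(w$offset, 0)
  expect_equal(w$data,
               s$signal[, (round(90 * fs) + 1):(round(100 * fs)), drop = FALSE])
  expect_warning(w2 <- test_window(s, make_probe(5, "p2"), "MW"), "dropped")
  expect_null(w2)
})

test_that("epochs never overlap rejected intervals", {
  fs <- 256
  s <- make_session(matrix(rnorm(1 * 120 * fs), 1), fs)
  s$rejected_intervals <- matrix(c(95, 96), ncol = 2)
  p <- make_probe(100, "p1")
  expect_warning(w <- augment_windows(s, p, "MW"), "dropped")
  # [90,100] and [87.5,97.5] and [85,95+2.5] overlap [95,96); [82.5,92.5] ok
  offs <- sapply(w, `[[`, "offset")
  expect_true(7.5 %in% offs)
  expect_false(0 %in% offs)
  for (e in w) {
    a <- 100 - e$offset - 10; b <- 100 - e$offset
    expect_false(a < 96 && 95 < b)
  }
  expect_warning(expect_null(test_window(s, p, "MW")))
})

test_that("epoch set carries one row per retained window with probe ids", {
  spec <- cohort_spec(n_participants = 1, n_blocks = 2, block_duration = 120,
                      sampling_rate = 256, n_channels = 2,
                      channel_labels = c("FP1", "O1"), seed = 14)
  s <- generate_session(spec, signal_model(), "S01")
  s$rejected_intervals <- matrix(numeric(0), ncol = 2)
  es <- build_epoch_set(s)
  expect_s3_class(es, "mw_epoch_set")
  expect_equal(length(es$epochs), nrow(es$meta))
  labs <- label_probe(s$probes$response, s$probes$confidence)
  kept <- s$probes$probe_id[labs != "excluded"]
  expect_true(all(es$meta$probe_id %in% kept))
  # every epoch is 2 x 2560 and offset-0 windows are flagged as test windows
  expect_true(all(sapply(es$epochs, ncol) == 2560))
  expect_identical(es$meta$is_test, es$meta$offset == 0)
  # per-probe window counts never exceed the class scheme
  cnt <- table(es$meta$probe_id)
  lab_by_probe <- es$meta$label[match(names(cnt), es$meta$probe_id)]
  expect_true(all(cnt[lab_by_probe == "MW"] <= 4))
  expect_true(all(cnt[lab_by_probe == "nonMW"] <= 2))
})

test_that("participants below 10% MW proportion are excluded, 10% kept", {
  tbl <- rbind(
    data.frame(participant_id = "A", label = c(rep("MW", 1), rep("nonMW", 19))),
    data.frame(participant_id = "B", label = c(rep("MW", 2), rep("nonMW", 18))),
    data.frame(participant_id = "C", label = c(rep("MW", 5), rep("nonMW", 13))))
  out <- filter_participants(tbl)
  expect_equal(out$removed, "A")           # 5% -> out
  expect_true("B" %in% out$kept)           # exactly 10% -> kept
  expect_true("C" %in% out$kept)           # 27.8% -> kept
  expect_equal(unname(out$proportions["C"]), 5 / 18)
  expect_error(filter_participants(tbl[0, ]), "empty")
})
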