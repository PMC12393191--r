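# Protocol validation, sub-TR arithmetic and echo-train timing.

test_that("sub-TR is TR over the slice count, with degenerate cases handled", {
  expect_equal(compute_sub_tr(fx$invivo), 3000 / 23, tolerance = 1e-12)
  cfg1 <- es_protocol(TR = 1200, n_slices = 1, n_echoes = 16, n_shifted = 0,
                      K = 0)
  expect_warning(out <- compute_sub_tr(cfg1), "shifting is impossible")
  expect_equal(out, 1200)
  cfg0 <- cfg1
  cfg0$n_slices <- 0
  expect_error(compute_sub_tr(cfg0), class = "es_validation_error")
})

test_that("protocol invariants are enforced with named validation errors", {
  expect_error(es_protocol(K = -1), "K", class = "es_validation_error")
  expect_error(es_protocol(n_echoes = 10, n_shifted = 10), "n_shifted",
               class = "es_validation_error")
  expect_error(es_protocol(TR = -5), "TR", class = "es_validation_error")
  # echo shifting needs a next sub-TR interval
  expect_error(es_protocol(n_slices = 1, n_shifted = 21),
               class = "es_validation_error")
  # a readout block that cannot fit one sub-TR is a timing overflow
  expect_error(es_protocol(TR = 100, n_slices = 4),
               class = "es_timing_overflow")
})

test_that("in vivo preset reproduces the published echo-train timing", {
  tr <- build_echo_train(fx$invivo, with_b = FALSE)
  expect_equal(nrow(tr), 64)
  expect_equal(sum(tr$shifted), 21)
  # printed TEs: 3 / 66.18 / 206.88 / 237.72 ms; slot arithmetic agrees to
  # raster rounding for the prompt block and to ~2% for the shifted block
  # (the echo-shift lobe duration is derived from K and the slew limit)
  expect_equal(tr$te[1], 3)
  expect_equal(tr$te[43], 66.18, tolerance = 0.002)
  expect_equal(tr$te[44], 206.88, tolerance = 0.02)
  expect_equal(tr$te[64], 237.72, tolerance = 0.02)
  # navigator in the shifted block adds one slot: TE64 - TE44 = 21 * dTE
  expect_equal(tr$te[64] - tr$te[44], 21 * 1.47, tolerance = 1e-9)
  # one intervening navigator makes consecutive shifted echoes 2 * dTE apart
  nav2_slot <- navigators(tr)$slot[2]
  before <- max(which(tr$slot < nav2_slot & tr$shifted))
  expect_equal(tr$te[before + 1] - tr$te[before], 2 * 1.47, tolerance = 1e-9)
  # all shifted TEs exceed the sub-TR interval
  expect_true(all(tr$te[tr$shifted] > attr(tr, "sub_tr")))
})

test_that("plain mGRE limit: no shifting, no navigators, exact slot TEs", {
  cfg <- es_protocol(TR = 1200, n_echoes = 16, n_shifted = 0, K = 0,
                     navigator_slots = integer(0))
  tr <- build_echo_train(cfg)
  expect_equal(tr$te, 3 + (0:15) * 1.47, tolerance = 1e-12)
  expect_false(any(tr$shifted))
  expect_equal(tr$polarity, rep(c(1, -1), 8))
})

test_that("TEs increase strictly within each block and navigators land in their blocks", {
  for (cfg in list(fx$cfg64, fx$invivo)) {
    tr <- build_echo_train(cfg, with_b = FALSE)
    expect_true(all(diff(tr$te[!tr$shifted]) > 0))
    expect_true(all(diff(tr$te[tr$shifted]) > 0))
    nav <- navigators(tr)
    expect_equal(nav$block, c("prompt", "shifted"))
  }
})

test_that("protocol YAML round trip and preset files agree with constructors", {
  tmp <- tempfile(fileext = ".yaml")
  write_protocol(fx$cfg64, tmp)
  back <- read_protocol(tmp)
  expect_equal(unclass(back), unclass(fx$cfg64))
  pre <- es_preset("table1_invivo")
  expect_equal(pre$n_slices, 23)
  expect_equal(pre$navigator_slots, c(16L, 49L))
  expect_equal(build_echo_train(pre, with_b = FALSE)$te,
               build_echo_train(fx$invivo, with_b = FALSE)$te)
  expect_error(read_protocol(tempfile()), class = "es_validation_error")
})

test_that("echo-train export round-trips through JSON and TSV", {
  tr <- fx$train64
  tmp <- tempfile(fileext = ".json")
  write_echo_train(tr, tmp)
  back <- read_echo_train(tmp)
  expect_equal(back$te, tr$te)
  expect_equal(back$b, tr$b)
  expect_equal(attr(back, "sub_tr"), attr(tr, "sub_tr"))
  tsv <- tempfile(fileext = ".tsv")
  write_echo_train(tr, tsv, format = "tsv")
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(df$te, tr$te)
})
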