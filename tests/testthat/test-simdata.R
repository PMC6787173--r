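test_that("simulate_well is deterministic and validates its inputs", {
  a <- simulate_well(channel_model(), n_events = 500, seed = 11)
  b <- simulate_well(channel_model(), n_events = 500, seed = 11)
  expect_identical(a, b)
  c <- simulate_well(channel_model(), n_events = 500, seed = 12)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 500)

  expect_error(channel_model(viability = 1.2), "viability")
  expect_error(channel_model(bead_mean = -1), "bead_mean")
  expect_error(channel_model(pi_neg_logsd = 0), "pi_neg_logsd")
  expect_error(effect_profile(phago_effect = 0), "phago_effect")
  expect_error(simulate_well(channel_model(), n_events = 0), "n_events")
})

test_that("without phagocytosis FITC is pure autofluorescence", {
  m <- channel_model(phago_prob = 1e-12, debris_fraction = 0)
  ev <- simulate_well(m, n_events = 1000, seed = 1)
  expect_true(all(ev$bead_count == 0))
  # lognormal autofluorescence upper tail: all events stay far below the
  # single-bead scale
  expect_lt(max(ev$FITC), exp(m$autofluor_logmean + 6 * m$autofluor_logsd))
})

test_that("hidden labels are internally consistent", {
  ev <- simulate_well(channel_model(), n_events = 20000, seed = 3)
  expect_true(all(ev$bead_count[!ev$is_viable] == 0))
  expect_true(all(!ev$is_viable[!ev$is_cell]))
  expect_true(all(!ev$is_transfected[!ev$is_viable]))
  expect_true(all(ev$FSC >= 0 & ev$SSC >= 0 & ev$PI >= 0 &
                    ev$AF647 >= 0 & ev$FITC >= 0))
})

test_that("NT calibration reproduces the planted rates at large n", {
  ev <- simulate_well(channel_model(), n_events = 1e5, seed = 42)
  viable <- ev$is_viable
  n_cells <- sum(ev$is_cell)
  frac_viable <- sum(viable) / n_cells
  expect_lt(abs(frac_viable - 0.80), 3 * sqrt(0.8 * 0.2 / n_cells))
  frac_trans <- sum(ev$is_transfected) / sum(viable)
  expect_lt(abs(frac_trans - 0.80), 3 * sqrt(0.8 * 0.2 / sum(viable)))
  frac_phago <- mean(ev$bead_count[viable] > 0)
  expect_lt(abs(frac_phago - 0.51), 3 * sqrt(0.51 * 0.49 / sum(viable)))
})

test_that("bead counts follow the zero-truncated Poisson law", {
  lambda <- 2
  m <- channel_model(phago_prob = 1, debris_fraction = 0, viability = 1,
                     bead_mean = lambda)
  ev <- simulate_well(m, n_events = 1e5, seed = 5)
  k <- ev$bead_count
  expect_true(all(k >= 1))
  # closed form for the zero-truncated mean
  zt_mean <- lambda / (1 - exp(-lambda))
  expect_equal(zt_mean, 2.313, tolerance = 1e-3)
  expect_lt(abs(mean(k) - zt_mean), 3 * sd(k) / sqrt(length(k)))
  # rejection-sampling oracle: mean and variance agree
  set.seed(99)
  oracle <- rztpois_rejection(1e5, lambda)
  se_mean <- sqrt(var(k) / length(k) + var(oracle) / length(oracle))
  expect_lt(abs(mean(k) - mean(oracle)), 3 * se_mean)
  expect_lt(abs(var(k) - var(oracle)) / var(oracle), 0.1)
})

test_that("effects act monotonically on the hidden ground truth", {
  # phago_effect: common random numbers make the effect pointwise monotone
  fr <- sapply(c(0.4, 0.8, 1.0, 1.5), function(e) {
    ev <- simulate_well(channel_model(),
                        effect_profile("x", phago_effect = e),
                        n_events = 2e4, seed = 7)
    mean(ev$bead_count[ev$is_viable] > 0)
  })
  expect_true(all(diff(fr) >= 0))
  # bead_effect raises the mean bead load, hence the FITC MFI of phagocytic
  # cells
  mfis <- sapply(c(0.5, 1, 2), function(e) {
    ev <- simulate_well(channel_model(),
                        effect_profile("x", bead_effect = e),
                        n_events = 3e4, seed = 8)
    mean(ev$FITC[ev$bead_count > 0])
  })
  expect_true(all(diff(mfis) > 0))
  # identity profile reproduces the NT model exactly
  expect_identical(
    simulate_well(channel_model(), effect_profile("NT"), 1000, seed = 2),
    simulate_well(channel_model(),
                  effect_profile("id", phago_effect = 1, bead_effect = 1),
                  1000, seed = 2)
  )
})

test_that("plate layouts place controls and triplicates as configured", {
  layout <- build_plate_layouts(80, nt_per_plate = 6, cytod_per_plate = 2,
                                untreated_per_plate = 1, replicates = 3)
  expect_equal(length(unique(layout$plate_id)), 3)
  expect_equal(sum(layout$role == "miRNA"), 240)
  counts <- table(layout$treatment_id[layout$role == "miRNA"])
  expect_true(all(counts == 3))
  # every miRNA confined to one plate
  per_mirna_plates <- tapply(layout$plate_id[layout$role == "miRNA"],
                             layout$treatment_id[layout$role == "miRNA"],
                             function(p) length(unique(p)))
  expect_true(all(per_mirna_plates == 1))
  for (p in unique(layout$plate_id)) {
    plate <- layout[layout$plate_id == p, ]
    expect_equal(sum(plate$role == "NT"), 6)
    expect_equal(sum(plate$role == "CytoD"), 2)
    expect_lte(nrow(plate), 96)
    expect_false(anyDuplicated(plate$well) > 0)
  }

  empty <- build_plate_layouts(0)
  expect_true(all(empty$role %in% c("NT", "CytoD", "untreated")))
  expect_error(build_plate_layouts(100, max_plates = 2), "max_plates")
  expect_error(build_plate_layouts(10, nt_per_plate = 2), "NT")
})

test_that("simulate_screen is seed-deterministic and honours the reduce hook", {
  s1 <- simulate_screen(4, seed = 21, n_events = 300)
  s2 <- simulate_screen(4, seed = 21, n_events = 300)
  expect_identical(s1, s2)
  expect_equal(length(s1$wells), nrow(s1$layout))
  expect_true(all(vapply(s1$wells, nrow, integer(1)) == 300))

  red <- simulate_screen(4, seed = 21, n_events = 300,
                         reduce = function(ev) gate_well(ev, gate_config()))
  full <- lapply(s1$wells, gate_well, cfg = gate_config())
  expect_identical(red$wells, full)
})

test_that("UTR fixtures plant the requested sites at recorded coordinates", {
  mir <- mirna("miR-124-5p", "CGUGUUCACAGCGGACCUUGAU")
  fx <- generate_utr_fixture(mir, n_sites = 8,
                             site_types = c("8mer", "7mer-m8", "7mer-A1",
                                            "6mer"),
                             seed = 13)
  expect_equal(nrow(fx$sites), 8)
  found <- scan_sites(mir, fx$utrs)
  merged <- merge(fx$sites, found,
                  by = c("seq_id", "start", "end", "site_type"))
  expect_equal(nrow(merged), nrow(fx$sites))  # 100% recall, correct class

  none <- generate_utr_fixture(mir, n_sites = 0, seed = 13)
  expect_equal(nrow(none$sites), 0)
  expect_error(generate_utr_fixture(mir, 1, site_types = "9mer"), "site type")
})
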