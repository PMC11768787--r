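test_that("subjects without tremor have zero tremor intervals", {
  cfg <- cohort_config(duration_s = 120)
  prof <- subject_profile("C1", has_tremor = FALSE, seed = 11, config = cfg)
  sub <- generate_subject(prof)
  expect_equal(sum(sub$annotations$label == "tremor"), 0L)
  expect_false(any(sub$annotations$sub_class %in% tremor_sub_classes()))
})

test_that("generation is a pure function of profile and seed", {
  cfg <- cohort_config(duration_s = 90)
  prof <- subject_profile("S", has_tremor = TRUE, tremor_freq_hz = 5,
                          seed = 42, config = cfg)
  a <- generate_subject(prof)
  b <- generate_subject(prof)
  expect_identical(as.data.frame(a$recording), as.data.frame(b$recording))
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
})

test_that("different master seeds change signals but not cohort shape", {
  cfg <- cohort_config(n_tremor = 1, n_pd_no_tremor = 1, n_control = 1,
                       duration_s = 60)
  a <- generate_cohort(cfg, master_seed = 1)
  b <- generate_cohort(cfg, master_seed = 2)
  expect_equal(nrow(a), 3L)
  expect_equal(nrow(b), 3L)
  # same recorded duration per subject, different signal content
  for (i in 1:3) {
    expect_equal(nrow(a$recording[[i]]), nrow(b$recording[[i]]))
    expect_false(isTRUE(all.equal(a$recording[[i]]$acc_x,
                                  b$recording[[i]]$acc_x)))
  }
  # pure function of (config, master_seed)
  a2 <- generate_cohort(cfg, master_seed = 1)
  expect_identical(as.data.frame(a$recording[[1]]),
                   as.data.frame(a2$recording[[1]]))
})

test_that("tremor episodes carry their fundamental frequency spectrally", {
  cfg <- cohort_config(duration_s = 180, tremor_amp_range = c(0.15, 0.15),
                       noise_sd_g = 0.005)
  prof <- subject_profile("S", has_tremor = TRUE, tremor_freq_hz = 5,
                          tremor_amp_g = 0.15, noise_sd_g = 0.005,
                          seed = 7, config = cfg)
  sub <- generate_subject(prof)
  ann <- sub$annotations
  tre <- ann[ann$label == "tremor" & ann$sub_class %in% paste0("T", 1:6), ]
  expect_gt(nrow(tre), 0L)
  rec <- sub$recording
  iv <- tre[1L, ]
  idx <- rec$time_s >= iv$start_s & rec$time_s < iv$end_s
  x <- rec$acc_x[idx] - mean(rec$acc_x[idx])
  sp <- stats::spec.pgram(ts(x, frequency = 200), plot = FALSE, taper = 0.1)
  band <- sp$freq >= 4 & sp$freq <= 8
  peak <- sp$freq[band][which.max(sp$spec[band])]
  expect_lt(abs(peak - 5), 0.5)
  # the 4-8 Hz peak is also the global (non-DC) maximum for strong tremor
  nz <- sp$freq > 0.5
  expect_true(sp$freq[nz][which.max(sp$spec[nz])] >= 4)
})

test_that("strong tremor intervals concentrate spectral power in 4-8 Hz", {
  # property over many seeded intervals with amplitude/noise >= 5
  hits <- 0L
  n_int <- 0L
  for (seed in 1:35) {
    cfg <- cohort_config(duration_s = 360,
                         tremor_amp_range = c(0.1, 0.15),
                         noise_sd_g = 0.01)
    prof <- subject_profile(sprintf("S%d", seed), has_tremor = TRUE,
                            tremor_freq_hz = 4.5 + 0.25 * (seed %% 10),
                            tremor_amp_g = 0.12, noise_sd_g = 0.01,
                            seed = seed, config = cfg)
    sub <- generate_subject(prof)
    ann <- sub$annotations
    tre <- ann[ann$label == "tremor" & ann$sub_class %in% paste0("T", 1:6), ]
    rec <- sub$recording
    for (j in seq_len(nrow(tre))) {
      idx <- rec$time_s >= tre$start_s[j] & rec$time_s < tre$end_s[j]
      # use the dominant tremor axis (largest variance after detrend)
      A <- cbind(rec$acc_x[idx], rec$acc_y[idx], rec$acc_z[idx])
      A <- scale(A, scale = FALSE)
      x <- A[, which.max(apply(A, 2, var))]
      sp <- stats::spec.pgram(ts(x, frequency = 200), plot = FALSE,
                              taper = 0.1)
      nz <- sp$freq > 0.5
      pk <- sp$freq[nz][which.max(sp$spec[nz])]
      n_int <- n_int + 1L
      if (pk >= 4 && pk <= 8) hits <- hits + 1L
    }
  }
  expect_gte(n_int, 100L)
  expect_gte(hits / n_int, 0.95)
})

test_that("the default cohort mirrors the study group sizes", {
  cfg <- cohort_config(duration_s = 600)
  expect_equal(cfg$n_tremor, 8L)
  expect_equal(cfg$n_pd_no_tremor, 16L)
  expect_equal(cfg$n_control, 24L)
  coh <- generate_cohort(cfg, master_seed = 3)
  expect_equal(nrow(coh), 48L)
  has_tremor_intervals <- vapply(coh$annotations, function(a) {
    any(a$label == "tremor")
  }, logical(1L))
  expect_equal(sum(has_tremor_intervals), 8L)
  # taxonomy coverage: all 13 scheduled sub-classes annotated, each with at
  # least one prototype interval cohort-wide (N5 is reserved for the hard
  # difficulty preset)
  all_ann <- dplyr::bind_rows(lapply(coh$annotations, as.data.frame))
  expect_true(all(c(tremor_sub_classes(),
                    setdiff(non_tremor_sub_classes(), "N5")) %in%
                    all_ann$sub_class[all_ann$prototype]))
})

test_that("difficulty presets behave as documented", {
  easy <- difficulty_presets("easy")
  hard <- difficulty_presets("hard")
  expect_false("N5" %in% easy$activities)
  expect_true("N5" %in% hard$activities)
  # hard tremor SNR below easy tremor SNR on generated data
  snr_of <- function(cfg, seed) {
    prof <- subject_profile("S", TRUE, tremor_freq_hz = 5,
                            tremor_amp_g = mean(cfg$tremor_amp_range),
                            noise_sd_g = cfg$noise_sd_g, seed = seed,
                            config = cfg)
    sub <- generate_subject(prof)
    ann <- sub$annotations
    rec <- sub$recording
    tre <- ann[ann$label == "tremor" & ann$sub_class %in% paste0("T", 1:6), ]
    idx <- rec$time_s >= tre$start_s[1] & rec$time_s < tre$end_s[1]
    rest <- ann[ann$sub_class == "N7", ]
    jdx <- rec$time_s >= rest$start_s[1] & rec$time_s < rest$end_s[1]
    var(rec$acc_x[idx] - mean(rec$acc_x[idx])) /
      var(rec$acc_x[jdx] - mean(rec$acc_x[jdx]))
  }
  cfg_e <- easy; cfg_e$duration_s <- 360
  cfg_h <- hard; cfg_h$duration_s <- 360
  expect_gt(snr_of(cfg_e, 5), snr_of(cfg_h, 5))
})

test_that("degenerate configurations error or warn", {
  cfg <- cohort_config(duration_s = 60)
  prof <- subject_profile("S", TRUE, seed = 1, config = cfg)
  prof$activity_schedule <- tibble::tibble(activity = character(),
                                           duration_s = numeric())
  expect_error(generate_subject(prof), regexp = "duration")
  cfg0 <- cohort_config(n_tremor = 0, n_pd_no_tremor = 1, n_control = 1,
                        duration_s = 30)
  expect_warning(generate_cohort(cfg0, master_seed = 1),
                 regexp = "prototypes")
})
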