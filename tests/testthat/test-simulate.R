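test_that("default templates respect class structure", {
  r <- default_template("rest")
  expect_equal(r$emg1_amplitude_uV, 0)
  expect_equal(r$emg2_amplitude_uV, 0)
  lq <- default_template("liquid")
  expect_true(all(diff(lq$ssw_onsets_s) > 0))
  expect_lte(lq$emg1_onset_s, lq$ssw_onsets_s[1])
  expect_gte(lq$emg2_onset_s, lq$ssw_onsets_s[1])
  expect_lte(lq$emg2_onset_s, lq$ssw_onsets_s[2])
  # consistency monotonicity: liquid < soft_food < dense_food
  sf <- default_template("soft_food"); df_ <- default_template("dense_food")
  expect_true(lq$emg1_duration_s < sf$emg1_duration_s &&
              sf$emg1_duration_s < df_$emg1_duration_s)
  expect_true(lq$emg1_amplitude_uV < sf$emg1_amplitude_uV &&
              sf$emg1_amplitude_uV < df_$emg1_amplitude_uV)
  sa <- default_template("silent_aspiration")
  expect_gte(sa$transit_scale, 1.5)
  expect_gt(sa$transit_scale, lq$transit_scale)
  expect_gt(sa$desync_jitter_s, 0)
  err <- tryCatch(default_template("espresso"), error = conditionMessage)
  expect_match(err, "silent_aspiration")   # message lists valid labels
})

test_that("render_event is seeded-deterministic and class-faithful", {
  a <- render_event(default_template("liquid"), 2000, seed = 7)
  b <- render_event(default_template("liquid"), 2000, seed = 7)
  expect_identical(a$emg_ch1, b$emg_ch1)
  expect_identical(a$sound, b$sound)
  expect_false(identical(
    a$sound, render_event(default_template("liquid"), 2000, seed = 8)$sound))
  expect_error(render_event(default_template("liquid"), 1000, 1), "2000")

  # rest renders at baseline level only
  ns <- default_noise_spec()
  r <- render_event(default_template("rest"), 2000, seed = 3)
  expect_lte(rms(r$sound), ns$sound_baseline * 1.5)

  # chewing: >= 3 rhythmic digastric bursts, 0.5-1 s apart, quiet sound
  ch <- render_event(default_template("chewing"), 2000, seed = 9)
  env <- abs(ch$emg_ch1)
  env <- stats::filter(env, rep(1 / 400, 400), sides = 2)  # 0.2 s smoother
  env[is.na(env)] <- 0
  pk <- which(diff(sign(diff(env))) == -2) + 1L
  pk <- pk[env[pk] > 0.5 * max(env)]
  # collapse plateau peaks closer than 0.3 s
  pk <- pk[c(TRUE, diff(pk) > 600)]
  expect_gte(length(pk), 3)
  gaps <- diff(pk) / 2000
  expect_true(all(gaps > 0.45 & gaps < 1.05))
  sw <- render_event(default_template("liquid"), 2000, seed = 9)
  expect_lt(max(abs(ch$sound)), 0.5 * max(abs(sw$sound)))
})

test_that("generate_session assembles annotated recordings correctly", {
  one <- generate_session(1, 5, class_mix = c(liquid = 1), seed = 1)
  expect_length(one, 1)
  ann <- one[[1]]$annotations
  expect_equal(nrow(ann), 5)
  expect_true(all(ann$class_label == "liquid"))
  # annotations ordered, disjoint, inside the recording
  expect_true(all(diff(ann$start_s) > 0))
  expect_true(all(ann$start_s[-1] >= ann$end_s[-5]))
  expect_lte(max(ann$end_s), length(one[[1]]$emg_ch1) / one[[1]]$fs_hz)

  many <- generate_session(4, 3, seed = 3)
  expect_length(many, 4)
  expect_equal(sum(vapply(many, function(r) nrow(r$annotations), 0L)), 12)
  expect_identical(vapply(many, `[[`, "", "participant_id"),
                   c("P01", "P02", "P03", "P04"))
  # determinism of the whole session
  again <- generate_session(4, 3, seed = 3)
  expect_identical(many[[2]]$sound, again[[2]]$sound)
  expect_identical(many[[3]]$annotations, again[[3]]$annotations)

  expect_error(generate_session(0, 5), ">= 1")
  expect_error(generate_session(1, 5, class_mix = c(liquid = 0.5)), "sum")
  expect_error(generate_session(1, 5, class_mix = numeric(0)), "empty")
})

test_that("powerline interference is present by default and removable", {
  ns0 <- default_noise_spec(); ns0$powerline_uV <- 0
  with_pl <- generate_session(1, 1, seed = 6)[[1]]
  no_pl <- generate_session(1, 1, noise_spec = ns0, seed = 6)[[1]]
  p60 <- function(x, fs) {
    n <- length(x)
    k <- round(60 * n / fs) + 1L
    Mod(stats::fft(x))[k]^2
  }
  gain_db <- 10 * log10(p60(with_pl$emg_ch1, 2000) /
                        p60(no_pl$emg_ch1, 2000))
  expect_gte(gain_db, 20)
})

test_that("normal swallows are synchronised; aspiration is not", {
  n_ok <- 0L
  for (s in 1:60) {
    tr <- render_event(default_template(sample(c("liquid", "soft_food",
                                                 "dense_food"), 1)),
                       2000, seed = s)$truth[[1]]
    ss <- tr$realized_ssw_onsets_s
    ok <- all(diff(ss) > 0) && tr$emg1_onset_s <= ss[1] &&
      tr$realized_emg2_onset_s >= ss[1] && tr$realized_emg2_onset_s <= ss[2]
    n_ok <- n_ok + ok
  }
  expect_equal(n_ok, 60L)   # synchronisation holds in 100% of normals

  n_viol <- 0L
  for (s in 1:60) {
    tr <- render_event(default_template("silent_aspiration"), 2000,
                       seed = s)$truth[[1]]
    ss <- tr$realized_ssw_onsets_s
    viol <- any(diff(ss) <= 0) ||
      tr$emg1_onset_s * tr$transit_scale > ss[1] ||
      tr$realized_emg2_onset_s < ss[1] || tr$realized_emg2_onset_s > ss[2]
    n_viol <- n_viol + viol
  }
  expect_gte(n_viol / 60, 0.5)
})
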