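test_that("noise-free limit: MAP equals targets and TOI equals plateau plus offset", {
  cfg <- noise_free_config()
  traj <- simulate_map_trajectory(cfg, "baseline", "phenylephrine", 0)
  targets <- c(60, 64, 69, 80, 109)
  expect_equal(as.numeric(tapply(traj$map_mmHg, traj$dose_ug_kg_min, unique)),
               targets)

  sim <- simulate_experiment(noise_free_config())
  # intact windows: constant TOI at plateau + condition offset whenever the
  # window-mean MAP sits on the plateau
  rec <- sim$recordings
  tr <- sim$truth
  profiles <- default_site_profiles()
  intact <- tr[tr$regime == "intact", ]
  for (i in seq_len(min(nrow(intact), 20))) {
    row <- intact[i, ]
    sub <- rec[rec$animal_id == row$animal_id & rec$condition == row$condition &
                 rec$drug == row$drug &
                 rec$dose_ug_kg_min == row$dose_ug_kg_min, ]
    prof <- profiles[[row$site]]
    m <- mean(sub$map_mmHg)
    if (m < prof$lower_limit_map || m > prof$upper_limit_map) next
    expected <- prof$plateau_toi + prof$condition_offsets[[row$condition]]
    expect_equal(unique(sub[[paste0("toi_", row$site, "_pct")]]), expected)
  }
})

test_that("identical configurations generate bit-identical experiments", {
  cfg <- sim_config(n_animals = 2, seed = 77)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(sim_config(n_animals = 2, seed = 77))
  expect_identical(as.data.frame(s1$recordings), as.data.frame(s2$recordings))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(sim_config(n_animals = 2, seed = 78))
  expect_false(identical(as.data.frame(s1$recordings),
                         as.data.frame(s3$recordings)))
})

test_that("noise-free regime slopes produce perfectly monotone TOI", {
  prof <- site_profile("cerebral", 65)
  map_ramp <- seq(55, 95, length.out = 60)
  up <- simulate_toi_from_map(map_ramp,
                              prof,
                              regime_spec("pressure_passive", 0.2, 0, 0),
                              "baseline")
  expect_true(all(diff(up) > 0))
  expect_equal(spearman_rho(map_ramp, up), 1)
  down <- simulate_toi_from_map(map_ramp,
                                prof,
                                regime_spec("paradoxical", -0.2, 0, 0),
                                "baseline")
  expect_equal(spearman_rho(map_ramp, down), -1)
})

test_that("default-config per-dose MAP grand means land on the targets", {
  sim <- simulate_experiment(sim_config(seed = 101))
  rec <- sim$recordings
  targets <- default_map_targets()
  arms <- protocol_arms(protocol_spec())
  for (j in seq_len(nrow(arms))) {
    sub <- rec[rec$condition == arms$condition[j] & rec$drug == arms$drug[j], ]
    gm <- tapply(sub$map_mmHg, sub$dose_ug_kg_min, mean)
    tg <- targets[targets$condition == arms$condition[j] &
                    targets$drug == arms$drug[j], ]
    tg <- tg[order(tg$dose_ug_kg_min), ]
    expect_true(all(abs(gm - tg$map_mmHg) < 2),
                label = paste(arms$condition[j], arms$drug[j]))
  }
})

test_that("across-animal spread of window means tracks the between-animal SD", {
  cfg <- sim_config(seed = 55, map_between_animal_sd = 3)
  sim <- simulate_experiment(cfg)
  rec <- sim$recordings
  sub <- rec[rec$condition == "baseline" & rec$drug == "phenylephrine" &
               rec$dose_ug_kg_min == 5, ]
  means <- tapply(sub$map_mmHg, sub$animal_id, mean)
  expect_gt(stats::sd(means), 3 * 0.5)
  expect_lt(stats::sd(means), 3 * 1.5)
})

test_that("site ordering: cerebral > lumbar > thoracic mean TOI at every dose", {
  sim <- simulate_experiment(sim_config(seed = 21))
  sm <- summarize_dose(sim$recordings)
  for (d in c(0, 0.5, 1, 2, 5)) {
    sub <- sm[sm$condition == "baseline" & sm$drug == "phenylephrine" &
                sm$dose_ug_kg_min == d, ]
    cer <- sub$mean[sub$variable == "toi_cerebral"]
    tho <- sub$mean[sub$variable == "toi_thoracic"]
    lum <- sub$mean[sub$variable == "toi_lumbar"]
    expect_true(cer > lum && lum > tho)
  }
})

test_that("degenerate configurations are guarded", {
  expect_error(sim_config(n_animals = 0), "n_animals")
  bad_rp <- default_regime_probabilities()
  bad_rp$intact[1] <- 0.9
  expect_error(sim_config(regime_probabilities = bad_rp), "sum to 1")
  expect_error(regime_spec("pressure_passive", -0.1), "inconsistent")
  expect_error(site_profile("cerebral", 65,
                            condition_offsets = c(baseline = 0,
                                                  hypovolemia = -10,
                                                  fluid_resuscitation = 0)),
               "5%")
  # MAP floor guard under absurd noise
  cfg <- sim_config(n_animals = 1, map_within_window_sd = 40, seed = 8)
  set.seed(8)
  traj <- simulate_map_trajectory(cfg, "baseline", "SNP", 0)
  expect_true(all(traj$map_mmHg >= 20))
  expect_gt(attr(traj, "n_floored"), 0)
})
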