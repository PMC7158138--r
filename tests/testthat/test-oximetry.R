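test_that("spearman_rho matches the textbook formula and mid-rank oracle exhaustively", {
  # no-ties: every permutation y of 1..n against x = 1..n, n up to 6
  for (n in 3:6) {
    perms <- cordox:::all_permutations(n)
    for (i in seq_len(nrow(perms))) {
      y <- perms[i, ]
      expect_equal(spearman_rho(seq_len(n), y),
                   spearman_d2_formula(seq_len(n), y), tolerance = 1e-12)
    }
  }
  # injected ties: x = (1,2,2,3) vs all permutations of (1,2,3,4), against a
  # mid-rank Pearson oracle
  x <- c(1, 2, 2, 3)
  perms <- cordox:::all_permutations(4)
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_rho worked examples and undefined markers", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman_rho(1:4, rep(5, 4))))    # zero variance
  expect_true(is.na(spearman_rho(1:2, 2:1)))          # n < 3
  expect_error(spearman_rho(1:4, 1:3), "equal length")
})

test_that("spearman_rho is symmetric, sign-flips, and is monotone-invariant", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(y, x), r, tolerance = 1e-12)
    expect_equal(spearman_rho(x, -y), -r, tolerance = 1e-12)
    expect_equal(spearman_rho(exp(x), y^3 + 5 * y), r, tolerance = 1e-12)
  }
})

test_that("classification partitions [-1, 1] with the boundary going to intact", {
  expect_equal(classify_response(0.5), "pressure_passive")
  expect_equal(classify_response(0.0), "intact")
  expect_equal(classify_response(-0.5), "paradoxical")
  expect_equal(classify_response(0.36), "intact")
  expect_equal(classify_response(-0.36), "intact")
  expect_equal(classify_response(NA_real_), "undefined")
  expect_error(classify_response(1.5), "outside")
  rho_grid <- seq(-1, 1, by = 0.001)
  states <- classify_response(rho_grid)
  expect_true(all(states %in% c("pressure_passive", "intact", "paradoxical")))
  # each computable rho maps to exactly one state, consistent with the rule
  expect_equal(states == "pressure_passive", rho_grid > 0.36)
  expect_equal(states == "paradoxical", rho_grid < -0.36)
})

test_that("index computation composes window extraction and classification", {
  ds <- make_recording(doses = 0,
                       map_fun = function(d, t) 60 + t / 60,
                       toi_fun = function(d, t, s) 64 + 0.2 * (t / 60))
  idx <- compute_oximetry_indices(extract_dose_windows(ds))
  expect_equal(idx$rho, 1)
  expect_equal(idx$state, "pressure_passive")
  expect_equal(idx$n, 60L)

  ds2 <- make_recording(doses = 0,
                        map_fun = function(d, t) 60 + t / 60,
                        toi_fun = function(d, t, s) 64 - 0.2 * (t / 60))
  idx2 <- compute_oximetry_indices(extract_dose_windows(ds2))
  expect_equal(idx2$rho, -1)
  expect_equal(idx2$state, "paradoxical")

  # constant TOI -> undefined, not intact
  ds3 <- make_recording(doses = 0, map_fun = function(d, t) 60 + t / 60)
  idx3 <- compute_oximetry_indices(extract_dose_windows(ds3))
  expect_equal(idx3$state, "undefined")
  expect_true(is.na(idx3$rho))
})

test_that("response-pattern counts tabulate states and keep undefined separate", {
  idx <- data.frame(animal_id = sprintf("A%02d", 1:10),
                    condition = "baseline", drug = "phenylephrine",
                    dose_ug_kg_min = 0.5, site = "cerebral", n = 60,
                    rho = c(0.5, 0.6, 0.7, 0.1, -0.1, 0, 0.2, -0.5, -0.6, -0.7),
                    stringsAsFactors = FALSE)
  idx$state <- classify_response(idx$rho)
  cnt <- count_response_patterns(idx)
  expect_equal(cnt$pressure_passive, 3)
  expect_equal(cnt$intact, 4)
  expect_equal(cnt$paradoxical, 3)
  expect_equal(cnt$undefined, 0)
  expect_equal(cnt$n_windows, 10)

  empty <- count_response_patterns(idx[0, ])
  expect_equal(nrow(empty), 0)

  # conservation on a full synthetic experiment: per-group counts sum to the
  # number of animals with the site present
  sim <- simulate_experiment(sim_config(n_animals = 4, seed = 12))
  indices <- compute_oximetry_indices(extract_dose_windows(sim$recordings))
  cnt2 <- count_response_patterns(indices)
  expect_true(all(cnt2$n_windows[cnt2$site != "lumbar"] == 4))
  expect_true(all(cnt2$n_windows[cnt2$site == "lumbar"] == 3))
  expect_equal(cnt2$pressure_passive + cnt2$intact + cnt2$paradoxical +
                 cnt2$undefined, cnt2$n_windows)
})

test_that("index summaries give median (even-n midpoint), range and animal count", {
  base <- data.frame(condition = "baseline", drug = "SNP",
                     dose_ug_kg_min = 1, site = "cerebral", n = 60,
                     stringsAsFactors = FALSE)
  mk <- function(rhos) {
    df <- base[rep(1, length(rhos)), ]
    df$animal_id <- sprintf("A%02d", seq_along(rhos))
    df$rho <- rhos
    df$state <- classify_response(rhos)
    df
  }
  s1 <- summarize_indices(mk(c(0.1, 0.5, 0.9)))
  expect_equal(c(s1$median_rho, s1$min_rho, s1$max_rho), c(0.5, 0.1, 0.9))
  s2 <- summarize_indices(mk(c(0.2, 0.4)))
  expect_equal(s2$median_rho, 0.3)
  s3 <- summarize_indices(mk(0.76))
  expect_equal(c(s3$median_rho, s3$min_rho, s3$max_rho), rep(0.76, 3))
  expect_equal(s3$n_animals, 1L)
  s4 <- summarize_indices(mk(c(NA, NA)))
  expect_true(s4$empty)
})

test_that("paradoxical tallies use the any-dose rule over arms and animals", {
  mk_idx <- function(animal, condition, drug, states) {
    data.frame(animal_id = animal, condition = condition, drug = drug,
               dose_ug_kg_min = c(0, 0.5, 1, 2)[seq_along(states)],
               site = "cerebral", n = 60, rho = 0, state = states,
               stringsAsFactors = FALSE)
  }
  one <- mk_idx("A01", "baseline", "phenylephrine",
                c("intact", "paradoxical", "intact", "pressure_passive"))
  t1 <- paradoxical_window_tally(one, "cerebral")
  expect_equal(t1$infusions_paradoxical, 1L)
  expect_equal(t1$infusions_total, 1L)
  expect_equal(t1$animals_paradoxical, 1L)

  none <- mk_idx("A01", "baseline", "phenylephrine", rep("intact", 4))
  t2 <- paradoxical_window_tally(none, "cerebral")
  expect_equal(t2$infusions_paradoxical, 0L)

  # constructed fixture: paradoxical at exactly one dose of one arm
  idx <- rbind(mk_idx("A01", "baseline", "phenylephrine", rep("intact", 4)),
               mk_idx("A01", "baseline", "SNP",
                      c("intact", "intact", "paradoxical", "intact")),
               mk_idx("A02", "baseline", "phenylephrine", rep("intact", 4)),
               mk_idx("A02", "baseline", "SNP", rep("pressure_passive", 4)))
  t3 <- paradoxical_window_tally(idx, "cerebral")
  expect_equal(t3$infusions_paradoxical, 1L)
  expect_equal(t3$infusions_total, 4L)
  expect_equal(t3$animals_paradoxical, 1L)
  expect_equal(t3$animals_total, 2L)
})

test_that("null calibration: intact windows with independent noise misclassify < 2%", {
  set.seed(31)
  prof <- site_profile("cerebral", 65)
  reg <- regime_spec("intact", 0, noise_sd = 1, ar_coefficient = 0)
  n_mis <- 0L
  n_rep <- 2000L
  for (i in seq_len(n_rep)) {
    map <- 60 + rnorm(60, 0, 3)
    toi <- simulate_toi_from_map(map, prof, reg, "baseline")
    if (classify_response(spearman_rho(map, toi)) != "intact")
      n_mis <- n_mis + 1L
  }
  expect_lt(n_mis / n_rep, 0.02)
})
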