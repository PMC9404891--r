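test_that("config validation names the offending field", {
  expect_error(troop_config(n_males = 1, n_females = 1), "n_males \\+ n_females")
  expect_error(troop_config(session_length = 0), "session_length")
  expect_error(troop_config(mean_proximity_fraction = 1.2),
               "mean_proximity_fraction")
  expect_error(troop_config(zero_inflation = -0.1), "zero_inflation")
  expect_error(troop_config(dominance_steepness = -1), "dominance_steepness")
})

test_that("roster generation is deterministic and matches the troop makeup", {
  ros <- make_roster(troop_config())
  expect_equal(nrow(ros), 27)
  expect_equal(sum(ros$sex == "male"), 12)
  expect_equal(sum(ros$sex == "female"), 15)
  expect_true(any(ros$n_relatives == 0)) # immigrant males
  expect_false(any(duplicated(ros$id)))
  ros2 <- make_roster(troop_config())
  expect_identical(ros, ros2)
  ros3 <- make_roster(troop_config(seed = 2))
  expect_false(identical(ros$true_gregariousness, ros3$true_gregariousness))
  # single shared matriline: everyone related to everyone
  all_kin <- make_roster(troop_config(n_males = 0, n_females = 6,
                                      n_matrilines = 1))
  expect_true(all(all_kin$n_relatives == 5))
})

test_that("proximity generator respects bounds and drives the DAI", {
  cfg <- troop_config()
  ros <- make_roster(cfg)
  none <- simulate_proximity(ros, troop_config(mean_proximity_fraction = 0))
  expect_true(all(none$overlap_s == 0))
  prox <- simulate_proximity(ros, cfg)
  expect_true(all(prox$overlap_s >= 0 &
                    prox$overlap_s <= prox$session_duration_s))
  dai <- compute_dai(prox, ros)
  off <- dai[upper.tri(dai)]
  expect_gt(mean(off), 0)
  # association rises with the product of latent gregariousness
  g <- ros$true_gregariousness
  gp <- outer(g, g)[upper.tri(dai)]
  expect_gt(cor(off, gp), 0.5)
})

test_that("agonistic generator spans coin flips to a strict hierarchy", {
  cfg_steep <- troop_config(dominance_steepness = 50, seed = 4)
  ros <- make_roster(cfg_steep)
  ds <- davids_score(simulate_agonistic(ros, cfg_steep), ros)
  # a (near-)deterministic ladder: DS strictly decreasing in latent rank
  expect_true(all(diff(ds$ds[order(ros$latent_rank)]) < 0))
  expect_equal(ds$rank[order(ros$latent_rank)], seq_len(27))
  # every dyad interacts, so DS is defined everywhere
  bouts <- simulate_agonistic(ros, cfg_steep)
  expect_equal(nrow(bouts), choose(27, 2) * cfg_steep$bouts_per_dyad)
  # steeper ladders spread the scores
  vars <- sapply(c(0, 1.5, 5), function(st) {
    cfg <- troop_config(dominance_steepness = st, seed = 4)
    var(davids_score(simulate_agonistic(ros, cfg), ros)$ds)
  })
  expect_true(all(diff(vars) > 0))
})

test_that("movement generator honours its degenerate settings", {
  ros <- make_roster(troop_config())
  silent_cfg <- troop_config(vocal_intercept = -30, vocal_sex_effect = 0,
                             vocal_centrality_effect = 0, order_effect = 0,
                             zero_inflation = 1, movement_count = 30)
  mv <- simulate_movements(ros, config = silent_cfg)
  expect_true(all(vapply(mv$events, function(e) sum(e$calls), numeric(1)) == 0))
  expect_equal(vocal_summary(mv$events)$n_vocal, 0)
  # all events have >= 3 participants and nondecreasing join times
  cfg <- troop_config(movement_count = 50, seed = 6)
  mv2 <- simulate_movements(ros, config = cfg)
  for (e in mv2$events) {
    expect_gte(nrow(e$joins), 3)
    expect_true(!is.unsorted(e$joins$join_time_s))
    expect_identical(e$initiator_id, e$joins$individual_id[1])
  }
  expect_identical(
    events_to_log(simulate_movements(ros, config = cfg)$events),
    events_to_log(mv2$events)) # same seed, same events
})

test_that("a positive order effect induces a positive order correlation", {
  cfg <- troop_config(movement_count = 500, order_effect = 1.5, seed = 8)
  ros <- make_roster(cfg)
  mv <- simulate_movements(ros, config = cfg)
  d <- mv$data
  rate <- tapply(d$n_calls, d$individual_id, sum) /
    tapply(d$n_calls, d$individual_id, length)
  mean_oi <- tapply(d$order_index, d$individual_id, mean)
  ids <- names(rate)
  expect_gt(spearman(as.numeric(mean_oi[ids]), as.numeric(rate[ids]))$rho, 0)
})

test_that("the paper_tally preset reproduces the movement tallies", {
  mv <- simulate_movements(read_table1_roster(), preset = "paper_tally")
  vs <- vocal_summary(mv$events)
  expect_equal(vs$n_events, 132L)
  expect_equal(vs$n_vocal, 52L)
  expect_equal(vs$n_nonvocal, 80L)
  expect_equal(vs$n_initiator_vocal, 34L)
  expect_true(all(vapply(mv$events, function(e) e$successful, logical(1))))
})

test_that("generated CSV fixtures round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- troop_config(movement_count = 15, n_sessions_per_individual = 2,
                      seed = 12)
  sim <- simulate_to_dir(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c("roster.csv", "proximity.csv",
                                               "agonistic.csv",
                                               "movements.csv")))))
  prox <- read.csv(file.path(dir, "proximity.csv"))
  expect_equal(unclass(compute_dai(prox, sim$roster)), unclass(sim$dai),
               tolerance = 1e-9)
  ev <- read_movement_log(file.path(dir, "movements.csv"))
  expect_length(ev, 15)
})
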