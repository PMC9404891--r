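#' Configuration of the synthetic troop generator
#'
#' Bundles all tunable parameters of the synthetic-data generators. Defaults
#' mirror the study conditions: 27 focal animals (12 males, 15 females),
#' 600 s focal sessions, 132 collective movements, a zero-heavy call count
#' process in which females and socially central individuals call more
#' (count-part effects on the log-rate scale equal to the fitted
#' social-factor model: sex 0.771, centrality 3.361).
#'
#' @param n_males,n_females numbers of male/female focal animals.
#' @param n_matrilines number of matrilines females are divided into.
#' @param session_length focal session length, seconds.
#' @param n_sessions_per_individual focal sessions per individual.
#' @param mean_proximity_fraction baseline expected fraction of a session a
#'   dyad spends within 1 m, in \[0, 1\].
#' @param dominance_steepness slope of the latent strength ladder feeding the
#'   agonistic generator; 0 gives coin-flip bouts, large values a strict
#'   linear hierarchy.
#' @param bouts_per_dyad agonistic bouts drawn per dyad (at least 1 so
#'   David's Score is defined everywhere).
#' @param movement_count number of collective movements to simulate.
#' @param mean_participants mean number of joiners per movement (minimum 3).
#' @param vocal_intercept intercept of the call-count log rate.
#' @param vocal_sex_effect additive log-rate effect of being female.
#' @param vocal_centrality_effect additive log-rate effect per unit
#'   eigenvector centrality.
#' @param order_effect additive log-rate effect per unit joining-order index.
#' @param zero_inflation probability of a structural zero in the call counts,
#'   in \[0, 1\].
#' @param family generative count law: `"zip"` or plain `"poisson"`.
#' @param seed master seed; every generator derives its own sub-stream.
#' @return List of class `troop_config`.
#' @export
troop_config <- function(n_males = 12L, n_females = 15L, n_matrilines = 3L,
                         session_length = 600, n_sessions_per_individual = 10L,
                         mean_proximity_fraction = 0.08,
                         dominance_steepness = 1.5, bouts_per_dyad = 6L,
                         movement_count = 132L, mean_participants = 8,
                         vocal_intercept = -2.8, vocal_sex_effect = 0.771,
                         vocal_centrality_effect = 3.361, order_effect = 1,
                         zero_inflation = 0.6, family = c("zip", "poisson"),
                         seed = 1L) {
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              n_matrilines = as.integer(n_matrilines),
              session_length = session_length,
              n_sessions_per_individual = as.integer(n_sessions_per_individual),
              mean_proximity_fraction = mean_proximity_fraction,
              dominance_steepness = dominance_steepness,
              bouts_per_dyad = as.integer(bouts_per_dyad),
              movement_count = as.integer(movement_count),
              mean_participants = mean_participants,
              vocal_intercept = vocal_intercept,
              vocal_sex_effect = vocal_sex_effect,
              vocal_centrality_effect = vocal_centrality_effect,
              order_effect = order_effect, zero_inflation = zero_inflation,
              family = match.arg(family), seed = as.integer(seed))
  if (cfg$n_males < 0) stop_config("n_males", "must be nonnegative")
  if (cfg$n_females < 0) stop_config("n_females", "must be nonnegative")
  if (cfg$n_males + cfg$n_females < 3) {
    stop_config("n_males + n_females", "must be at least 3")
  }
  if (cfg$n_matrilines < 1) stop_config("n_matrilines", "must be at least 1")
  if (!(cfg$session_length > 0)) stop_config("session_length", "must be positive")
  if (cfg$n_sessions_per_individual < 1) {
    stop_config("n_sessions_per_individual", "must be at least 1")
  }
  if (cfg$mean_proximity_fraction < 0 || cfg$mean_proximity_fraction > 1) {
    stop_config("mean_proximity_fraction", "must lie in [0, 1]")
  }
  if (cfg$dominance_steepness < 0) {
    stop_config("dominance_steepness", "must be nonnegative")
  }
  if (cfg$bouts_per_dyad < 1) stop_config("bouts_per_dyad", "must be at least 1")
  if (cfg$movement_count < 0) stop_config("movement_count", "must be nonnegative")
  if (cfg$mean_participants < 3) stop_config("mean_participants", "must be at least 3")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1) {
    stop_config("zero_inflation", "must lie in [0, 1]")
  }
  class(cfg) <- "troop_config"
  cfg
}

#' Generate a synthetic troop roster
#'
#' Deterministically (given the config seed) builds a roster of individuals
#' with sex, matriline membership, relative counts, a latent gregariousness
#' (the sociability used by the proximity and movement generators) and a
#' latent strength rank (used by the agonistic generator). Females all belong
#' to matrilines; each male is an immigrant with no relatives with
#' probability 3/4, so relative counts of 0 always occur.
#'
#' @param config a [troop_config()].
#' @return data.frame with columns `id`, `sex`, `matriline`, `n_relatives`,
#'   `true_gregariousness`, `latent_rank`.
#' @export
make_roster <- function(config = troop_config()) {
  stopifnot(inherits(config, "troop_config"))
  with_seed(sub_seed(config$seed, "roster"), {
    nm <- config$n_males; nf <- config$n_females
    n <- nm + nf
    ids <- c(sprintf("M%02d", seq_len(nm)), sprintf("F%02d", seq_len(nf)))
    sex <- c(rep("male", nm), rep("female", nf))
    lines <- paste0("L", seq_len(config$n_matrilines))
    mat <- rep(NA_character_, n)
    if (nf > 0) {
      # multinomial assignment: matriline sizes vary between draws, so the
      # relative count is never a deterministic function of sex
      mat[sex == "female"] <- sample(lines, nf, replace = TRUE)
      if (config$n_matrilines == 1) mat[sex == "female"] <- lines[1]
    }
    if (nm > 0) {
      migrant <- stats::runif(nm) < 0.75
      migrant[1] <- TRUE # always at least one immigrant (relative count 0)
      if (nm >= 2 && all(migrant) && nf > 0) migrant[nm] <- FALSE
      mat[which(sex == "male")[!migrant]] <-
        sample(lines, sum(!migrant), replace = TRUE)
    }
    roster <- data.frame(id = ids, sex = sex, matriline = mat,
                         stringsAsFactors = FALSE)
    roster$n_relatives <- as.integer(count_relatives(roster))
    roster$true_gregariousness <- stats::rlnorm(n, 0, 0.6)
    roster$latent_rank <- sample(n)
    roster
  })
}

# latent strength ladder in [-1, 1], decreasing in latent rank (rank 1
# strongest); rosters without generator latents fall back to a printed
# dominance rank, then to roster order
latent_strength <- function(roster) {
  n <- nrow(roster)
  rk <- roster$latent_rank
  if (is.null(rk)) rk <- roster$social_rank
  if (is.null(rk)) rk <- seq_len(n)
  seq(1, -1, length.out = n)[rk]
}

# latent sociability; rosters without it (e.g. the bundled study roster) get
# uniform gregariousness
roster_greg <- function(roster) {
  g <- roster$true_gregariousness
  if (is.null(g)) rep(1, nrow(roster)) else g
}

#' Simulate focal proximity records
#'
#' For every focal session of every individual, draws the 1 m proximity
#' duration with each partner. The expected dyadic fraction scales with the
#' product of the two individuals' latent gregariousness, so the downstream
#' DAI increases in it by construction.
#'
#' @param roster a [make_roster()] result.
#' @param config a [troop_config()].
#' @return data.frame with columns `focal_id`, `partner_id`, `session_id`,
#'   `session_duration_s`, `overlap_s` (one row per focal session x partner).
#' @export
simulate_proximity <- function(roster, config = troop_config()) {
  stopifnot(nrow(roster) > 0)
  n <- nrow(roster)
  g <- roster_greg(roster)
  gbar2 <- mean(g)^2
  with_seed(sub_seed(config$seed, "proximity"), {
    rows <- vector("list", n * config$n_sessions_per_individual)
    r <- 0L
    for (i in seq_len(n)) {
      for (s in seq_len(config$n_sessions_per_individual)) {
        p <- pmin(config$mean_proximity_fraction * g[i] * g[-i] / gbar2, 0.95)
        noise <- 2 * stats::rbeta(n - 1, 4, 4)
        overlap <- pmin(config$session_length * p * noise, config$session_length)
        r <- r + 1L
        rows[[r]] <- data.frame(
          focal_id = roster$id[i], partner_id = roster$id[-i],
          session_id = sprintf("%s-S%03d", roster$id[i], s),
          session_duration_s = config$session_length,
          overlap_s = overlap, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulate agonistic bouts
#'
#' Every dyad interacts `bouts_per_dyad` times; the probability that the
#' stronger individual wins follows a logistic ladder with slope
#' `dominance_steepness` on the latent strength difference. Steepness 0 gives
#' fair coin flips; large steepness a deterministic linear hierarchy.
#'
#' @inheritParams simulate_proximity
#' @return data.frame with columns `actor_id` (winner), `receiver_id`.
#' @export
simulate_agonistic <- function(roster, config = troop_config()) {
  stopifnot(nrow(roster) >= 2)
  s <- latent_strength(roster)
  n <- nrow(roster)
  with_seed(sub_seed(config$seed, "agonistic"), {
    pairs <- utils::combn(n, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      p_i <- stats::plogis(config$dominance_steepness * 4 * (s[i] - s[j]))
      wins_i <- stats::runif(config$bouts_per_dyad) < p_i
      data.frame(actor_id = ifelse(wins_i, roster$id[i], roster$id[j]),
                 receiver_id = ifelse(wins_i, roster$id[j], roster$id[i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

zip_draw <- function(n, lambda, pi0, family) {
  y <- stats::rpois(n, lambda)
  if (family == "zip" && pi0 > 0) {
    y[stats::runif(n) < pi0] <- 0L
  }
  y
}

#' Simulate collective movements with per-individual call counts
#'
#' Each movement draws at least 3 participants (weighted by gregariousness),
#' join times with exponential gaps, and per-participant call counts from a
#' zero-inflated Poisson whose log rate is `vocal_intercept +
#' vocal_sex_effect * female + vocal_centrality_effect * centrality +
#' order_effect * order_index`. An event is vocal iff any participant called.
#' The generating coefficients are returned alongside the events so parameter
#' recovery can be tested.
#'
#' With `preset = "paper_tally"` the stochastic generator is bypassed and a
#' deterministic 132-event fixture is returned in which 52 events are vocal
#' and in 34 of those the initiator is among the callers.
#'
#' @param roster a [make_roster()] result (or any data.frame with `id`,
#'   `sex`, `n_relatives`).
#' @param centrality named per-individual centrality scores (e.g. from
#'   [eigenvector_centrality()]); defaults to equal scores.
#' @param config a [troop_config()].
#' @param ranks optional named dominance ranks joined into the model frame.
#' @param preset `"none"` or `"paper_tally"`.
#' @return List with `events` (list of `movement_event`), `data` (one row per
#'   event x participant: the model frame for [fit_zip()]), and `truth` (the
#'   generating parameters).
#' @export
simulate_movements <- function(roster, centrality = NULL,
                               config = troop_config(), ranks = NULL,
                               preset = c("none", "paper_tally")) {
  preset <- match.arg(preset)
  if (preset == "paper_tally") return(paper_tally_movements(roster))
  n <- nrow(roster)
  if (is.null(centrality)) {
    centrality <- stats::setNames(rep(1 / sqrt(n), n), roster$id)
  }
  if (is.null(ranks)) {
    rk <- roster$latent_rank
    if (is.null(rk)) rk <- roster$social_rank
    if (is.null(rk)) rk <- seq_len(n)
    ranks <- stats::setNames(rk, roster$id)
  }
  female <- as.numeric(roster$sex == "female")
  g <- roster_greg(roster)
  cfg <- config
  with_seed(sub_seed(cfg$seed, "movements"), {
    events <- vector("list", cfg$movement_count)
    data_rows <- vector("list", cfg$movement_count)
    t_base <- 0
    for (e in seq_len(cfg$movement_count)) {
      N <- min(n, 3L + stats::rpois(1, max(cfg$mean_participants - 3, 0)))
      part <- sample.int(n, N, prob = g)
      gaps <- pmin(stats::rexp(N - 1, rate = 1 / 30), 290)
      times <- t_base + c(0, cumsum(gaps))
      t_base <- times[N] + 1000 # > 300 s: events stay separable as a stream
      oi <- order_index(seq_len(N), N)
      lam <- exp(cfg$vocal_intercept + cfg$vocal_sex_effect * female[part] +
                   cfg$vocal_centrality_effect * centrality[roster$id[part]] +
                   cfg$order_effect * oi)
      calls <- zip_draw(N, lam, cfg$zero_inflation, cfg$family)
      events[[e]] <- structure(list(
        event_id = e,
        joins = data.frame(individual_id = roster$id[part],
                           join_time_s = times, position = seq_len(N),
                           stringsAsFactors = FALSE),
        initiator_id = roster$id[part[1]],
        calls = stats::setNames(as.numeric(calls), roster$id[part]),
        successful = N >= 3
      ), class = "movement_event")
      data_rows[[e]] <- data.frame(
        event_id = e, individual_id = roster$id[part],
        sex = roster$sex[part],
        centrality = as.numeric(centrality[roster$id[part]]),
        rank = as.numeric(ranks[roster$id[part]]),
        relatives = roster$n_relatives[part],
        order_index = oi, n_calls = calls, exposure = 1,
        stringsAsFactors = FALSE)
    }
    list(events = events,
         data = do.call(rbind, c(data_rows, list(make.row.names = FALSE))),
         truth = list(intercept = cfg$vocal_intercept,
                      sex = cfg$vocal_sex_effect,
                      centrality = cfg$vocal_centrality_effect,
                      order = cfg$order_effect,
                      zero_inflation = cfg$zero_inflation,
                      family = cfg$family))
  })
}

# Deterministic fixture reproducing the study's movement tallies: 132
# successful events, 52 vocal, initiator vocal in 34 of the vocal events.
paper_tally_movements <- function(roster = read_table1_roster()) {
  ids <- as.character(roster$id)
  n <- length(ids)
  events <- vector("list", 132L)
  for (e in seq_len(132L)) {
    N <- 3L + (e - 1L) %% 4L # 3..6 participants, cycling
    part <- ids[(((e - 1L) * 3L) + seq_len(N) - 1L) %% n + 1L]
    calls <- stats::setNames(numeric(N), part)
    if (e <= 34L) {
      calls[1] <- 1 + (e %% 2L) # initiator calls
      if (e %% 3L == 0L) calls[2] <- 1
    } else if (e <= 52L) {
      calls[2] <- 1 + (e %% 2L) # only a follower calls
    }
    times <- (e - 1L) * 3600 + (seq_len(N) - 1L) * 60
    events[[e]] <- structure(list(
      event_id = e,
      joins = data.frame(individual_id = part, join_time_s = times,
                         position = seq_len(N), stringsAsFactors = FALSE),
      initiator_id = part[1],
      calls = calls,
      successful = TRUE
    ), class = "movement_event")
  }
  list(events = events, data = NULL,
       truth = list(n_events = 132L, n_vocal = 52L, n_initiator_vocal = 34L))
}

#' Read the bundled study roster
#'
#' The printed characteristics of the 27 focal animals (id, sex, relative
#' count, dominance rank and David's Score), shipped as a plain-text fixture.
#' Matriline labels are reconstructed from the relative counts and are
#' synthetic in that sense.
#'
#' @return data.frame with columns `id`, `sex`, `matriline`, `n_relatives`,
#'   `social_rank`, `ds`.
#' @export
read_table1_roster <- function() {
  path <- system.file("extdata", "table1_roster.csv", package = "troopcall")
  if (path == "") { # package not installed (e.g. sourced): fall back to tree
    path <- file.path("inst", "extdata", "table1_roster.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(matriline = "character"))
}

#' Write the synthetic dataset of a config to CSV files
#'
#' Runs all generators and writes `roster.csv`, `proximity.csv`,
#' `agonistic.csv`, `movements.csv` into `out_dir`.
#'
#' @param config a [troop_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the generated objects.
#' @export
simulate_to_dir <- function(config = troop_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roster <- make_roster(config)
  prox <- simulate_proximity(roster, config)
  ago <- simulate_agonistic(roster, config)
  dai <- compute_dai(prox, roster)
  cent <- eigenvector_centrality(dai)
  ds <- davids_score(ago, roster)
  mv <- simulate_movements(roster, cent, config,
                           ranks = stats::setNames(ds$rank, ds$id))
  write_if_changed(roster, file.path(out_dir, "roster.csv"))
  write_if_changed(prox, file.path(out_dir, "proximity.csv"))
  write_if_changed(ago, file.path(out_dir, "agonistic.csv"))
  write_if_changed(events_to_log(mv$events), file.path(out_dir, "movements.csv"))
  invisible(list(roster = roster, proximity = prox, agonistic = ago,
                 dai = dai, centrality = cent, dominance = ds,
                 movements = mv))
}
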