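#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> acoustics -> social -> movements -> stats and
#' assembles a report mirroring the study's result tables: (a) a call-type
#' table of acoustic parameters, (b) vocal/non-vocal movement tallies, (c)
#' the participants-with-vs-without-vocalization rank test, (d) the
#' joining-order vs vocal-frequency correlation, and (e) the social-factor
#' count model. All tabular outputs are written as header-bearing CSV into
#' `out_dir`; a stage whose inputs and outputs are unchanged is a no-op
#' (outputs are only rewritten when their bytes change).
#'
#' @param config a [troop_config()]; its seed drives every stage.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "acoustics", "social", "movements", "stats")`. Later
#'   stages read the CSV artifacts of earlier ones from `out_dir`, so an
#'   earlier stage must have run (now or previously) for a later one to work.
#' @param preset `"none"` or `"paper_tally"` (the deterministic 132-movement
#'   fixture on the bundled study roster).
#' @param call_jitter multiplicative jitter for the synthesized call set in
#'   the acoustics stage.
#' @param report_format `"csv"` (tables only) or `"markdown"` (also writes
#'   `report.md`).
#' @param verbose log stage progress to stderr.
#' @return An object of class `troopcall_report` (list with elements
#'   `call_table`, `tallies`, `participants_test`, `order_correlation`,
#'   `model_table`, plus `config` and `out_dir`).
#' @export
run_pipeline <- function(config = troop_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "acoustics", "social",
                                    "movements", "stats"),
                         preset = c("none", "paper_tally"),
                         call_jitter = 0.02,
                         report_format = c("csv", "markdown"),
                         verbose = TRUE) {
  preset <- match.arg(preset)
  report_format <- match.arg(report_format)
  known <- c("simulate", "acoustics", "social", "movements", "stats")
  if (length(stages) == 0) stop("no stages enabled")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[troopcall] ", sprintf(...))
  report <- list(config = config, out_dir = out_dir)

  need <- function(file, stage) {
    path <- file.path(out_dir, file)
    if (!file.exists(path)) {
      stop(sprintf("missing artifact %s: run stage '%s' first", file, stage))
    }
    path
  }

  if ("simulate" %in% stages) {
    log_msg("simulate: seed %d, %d movements%s", config$seed,
            config$movement_count,
            if (preset == "paper_tally") " (paper_tally preset)" else "")
    if (preset == "paper_tally") {
      roster <- read_table1_roster()
      mv <- simulate_movements(roster, config = config, preset = "paper_tally")
      cfg2 <- config
      write_if_changed(roster, file.path(out_dir, "roster.csv"))
      write_if_changed(simulate_proximity(roster, cfg2),
                       file.path(out_dir, "proximity.csv"))
      write_if_changed(simulate_agonistic(roster, cfg2),
                       file.path(out_dir, "agonistic.csv"))
      write_if_changed(events_to_log(mv$events),
                       file.path(out_dir, "movements.csv"))
    } else {
      sim <- simulate_to_dir(config, out_dir)
      write_if_changed(sim$movements$data,
                       file.path(out_dir, "movement_model_frame.csv"))
    }
    log_msg("simulate: wrote roster/proximity/agonistic/movements CSVs")
  }

  if ("acoustics" %in% stages) {
    set <- synthesize_call_set(jitter = call_jitter, seed = config$seed)
    feats <- lapply(set$waveforms, extract_features)
    cls <- vapply(feats, function(f) classify_call(f)$type, character(1))
    tab <- do.call(rbind, lapply(unique(set$types), function(ty) {
      m <- do.call(rbind, lapply(feats[cls == ty], function(f) {
        unlist(f[feature_names])
      }))
      if (is.null(m)) return(NULL)
      data.frame(call_type = ty, n = nrow(m), t(colMeans(m)),
                 stringsAsFactors = FALSE)
    }))
    report$call_table <- tab
    write_if_changed(tab, file.path(out_dir, "call_table.csv"))
    log_msg("acoustics: %d calls -> %s", length(cls),
            paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                  collapse = ", "))
  }

  if ("social" %in% stages) {
    roster <- utils::read.csv(need("roster.csv", "simulate"),
                              stringsAsFactors = FALSE,
                              colClasses = c(matriline = "character"))
    prox <- utils::read.csv(need("proximity.csv", "simulate"),
                            stringsAsFactors = FALSE)
    ago <- utils::read.csv(need("agonistic.csv", "simulate"),
                           stringsAsFactors = FALSE)
    dai <- compute_dai(prox, roster)
    cent <- eigenvector_centrality(dai)
    ds <- davids_score(ago, roster)
    rel <- count_relatives(roster)
    dai_df <- as.data.frame(unclass(dai))
    dai_df <- cbind(id = rownames(dai_df), dai_df)
    write_if_changed(dai_df, file.path(out_dir, "dai_matrix.csv"))
    write_if_changed(data.frame(id = names(cent),
                                centrality = as.numeric(cent)),
                     file.path(out_dir, "centrality.csv"))
    write_if_changed(ds, file.path(out_dir, "dominance.csv"))
    write_if_changed(data.frame(id = names(rel), n_relatives = as.integer(rel)),
                     file.path(out_dir, "relatives.csv"))
    log_msg("social: DAI %dx%d, centrality eigenvalue %.4f", nrow(dai),
            ncol(dai), attr(cent, "eigenvalue"))
  }

  if ("movements" %in% stages) {
    events <- read_movement_log(need("movements.csv", "simulate"))
    vs <- vocal_summary(events)
    oi <- order_index_table(events)
    pc <- participant_counts(events)
    report$tallies <- vs
    write_if_changed(data.frame(
      n_events = vs$n_events, n_vocal = vs$n_vocal,
      n_nonvocal = vs$n_nonvocal, pct_vocal = vs$pct_vocal,
      pct_nonvocal = vs$pct_nonvocal,
      n_initiator_vocal = vs$n_initiator_vocal,
      pct_initiator_vocal_of_vocal = vs$pct_initiator_vocal_of_vocal),
      file.path(out_dir, "events_summary.csv"))
    write_if_changed(oi, file.path(out_dir, "order_index.csv"))
    write_if_changed(vs$rates, file.path(out_dir, "vocal_rates.csv"))
    write_if_changed(pc, file.path(out_dir, "participant_counts.csv"))
    log_msg("movements: %d events, %d vocal (%.1f%%)", vs$n_events,
            vs$n_vocal, vs$pct_vocal)
  }

  if ("stats" %in% stages) {
    events <- read_movement_log(need("movements.csv", "movements"))
    vs <- vocal_summary(events)
    pc <- participant_counts(events)
    # (c) participants with vs without vocal communication
    if (length(unique(pc$vocal)) == 2) {
      mw <- mann_whitney(pc$n_participants[pc$vocal],
                         pc$n_participants[!pc$vocal], mode = "auto")
    } else mw <- NULL
    report$participants_test <- mw
    # (d) per-individual mean order index vs vocal frequency
    oi <- order_index_table(events)
    mean_oi <- tapply(oi$order_index, oi$individual_id, mean)
    rates <- vs$rates
    common <- intersect(names(mean_oi), rates$individual_id)
    sp <- if (length(common) >= 3) {
      spearman(as.numeric(mean_oi[common]),
               rates$vocal_frequency[match(common, rates$individual_id)])
    } else NULL
    report$order_correlation <- sp
    # (e) social-factor count model on per-event participant counts
    roster <- utils::read.csv(need("roster.csv", "simulate"),
                              stringsAsFactors = FALSE,
                              colClasses = c(matriline = "character"))
    cent_df <- utils::read.csv(need("centrality.csv", "social"),
                               stringsAsFactors = FALSE)
    dom <- utils::read.csv(need("dominance.csv", "social"),
                           stringsAsFactors = FALSE)
    rel <- utils::read.csv(need("relatives.csv", "social"),
                           stringsAsFactors = FALSE)
    frame <- events_to_log(events)
    frame$sex <- roster$sex[match(frame$individual_id, roster$id)]
    frame$female <- as.numeric(frame$sex == "female")
    frame$centrality <- cent_df$centrality[match(frame$individual_id, cent_df$id)]
    frame$rank <- dom$rank[match(frame$individual_id, dom$id)]
    frame$relatives <- rel$n_relatives[match(frame$individual_id, rel$id)]
    fit <- tryCatch(
      fit_zip(frame$n_calls,
              frame[, c("female", "rank", "relatives", "centrality")],
              family = config$family),
      error = function(e) e)
    if (inherits(fit, "error")) {
      log_msg("stats: count model failed (%s)", conditionMessage(fit))
      report$model_table <- NULL
    } else {
      report$model_table <- fit
      tab <- fit$coefficients
      names(tab) <- c("factor", "estimate", "se", "z", "p")
      write_if_changed(tab, file.path(out_dir, "model_table.csv"))
    }
    if (!is.null(mw)) {
      write_if_changed(data.frame(W = mw$W, U = mw$U, p = mw$p_value,
                                  method = mw$method),
                       file.path(out_dir, "participants_test.csv"))
    }
    if (!is.null(sp)) {
      write_if_changed(data.frame(n = sp$n, rho = sp$rho, p = sp$p_value),
                       file.path(out_dir, "order_correlation.csv"))
    }
    log_msg("stats: wrote model_table/participants_test/order_correlation")
  }

  class(report) <- "troopcall_report"
  if (report_format == "markdown") {
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

format_report_md <- function(r) {
  out <- c("# troopcall run report", "")
  if (!is.null(r$call_table)) {
    out <- c(out, "## Call types", "",
             utils::capture.output(print(r$call_table, row.names = FALSE)), "")
  }
  if (!is.null(r$tallies)) {
    t <- r$tallies
    out <- c(out, "## Movement tallies", "",
             sprintf("- %d successful movements; %d vocal (%.1f%%), %d non-vocal (%.1f%%)",
                     t$n_events, t$n_vocal, t$pct_vocal, t$n_nonvocal,
                     t$pct_nonvocal),
             sprintf("- initiator vocal in %d of the vocal movements (%.1f%%)",
                     t$n_initiator_vocal, t$pct_initiator_vocal_of_vocal), "")
  }
  if (!is.null(r$participants_test)) {
    p <- r$participants_test
    out <- c(out, "## Participants with vs without vocalization", "",
             sprintf("- Mann-Whitney U test: W = %g, p = %.4g", p$W,
                     p$p_value), "")
  }
  if (!is.null(r$order_correlation)) {
    s <- r$order_correlation
    out <- c(out, "## Joining order and vocal frequency", "",
             sprintf("- Spearman rank correlation: N = %d, r = %.3f, p = %.4g",
                     s$n, s$rho, s$p_value), "")
  }
  if (!is.null(r$model_table)) {
    out <- c(out, "## Social-factor count model", "",
             utils::capture.output(print(r$model_table)), "")
  }
  out
}

#' @export
print.troopcall_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
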