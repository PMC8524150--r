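## Task engine: trial schedules, the SSD staircase, session execution.

#' Construct a paradigm configuration
#'
#' @param species_variant `"pigeon"` or `"human"`.
#' @param n_trials Trials per session.
#' @param fraction_go,fraction_scd0,fraction_scd300 Trial-type proportions
#'   (must sum to 1).
#' @param scd_values Ascending SCD values in ms.
#' @param ssd_initial,ssd_step,ssd_min,ssd_max Staircase settings in ms.
#' @param go_response_window Response deadline in ms.
#' @param intertrial_interval,punishment_timeout Timing constants in ms.
#' @param staircase_success_criterion `"inhibit_only"` or
#'   `"inhibit_and_change"`.
#' @param n_sessions Sessions per subject (staircase carried across).
#' @param metadata Free-form provenance list.
#' @return A [ParadigmConfig-class].
#' @export
paradigmConfig <- function(species_variant, n_trials,
                           fraction_go = 0.70, fraction_scd0 = 0.15,
                           fraction_scd300 = 0.15,
                           scd_values = c(0, 300),
                           ssd_initial, ssd_step = 50,
                           ssd_min = 0, ssd_max = go_response_window,
                           go_response_window,
                           intertrial_interval, punishment_timeout = 0,
                           staircase_success_criterion, n_sessions = 1L,
                           metadata = list()) {
  new("ParadigmConfig",
      species_variant = species_variant, n_trials = as.integer(n_trials),
      fraction_go = fraction_go, fraction_scd0 = fraction_scd0,
      fraction_scd300 = fraction_scd300, scd_values = scd_values,
      ssd_initial = ssd_initial, ssd_step = ssd_step,
      ssd_min = ssd_min, ssd_max = ssd_max,
      go_response_window = go_response_window,
      intertrial_interval = intertrial_interval,
      punishment_timeout = punishment_timeout,
      staircase_success_criterion = staircase_success_criterion,
      n_sessions = as.integer(n_sessions), metadata = metadata)
}

#' Shipped paradigm presets
#'
#' `"pigeon"`: 400 trials per session, five sessions, 70/15/15 GO/SCD0/SCD300
#' composition, SSD starting at 450 ms with 50 ms steps, 5 s intertrial
#' interval and 5 s punishment timeout, staircase success = withheld GO
#' response. `"human"`: 864 trials in one session, SSD starting at 250 ms,
#' 2500 ms response window, 900 ms intertrial interval, staircase success =
#' withheld GO response plus a correct CHANGE response.
#'
#' @param species `"pigeon"` or `"human"`.
#' @return A [ParadigmConfig-class].
#' @examples
#' paradigmPreset("pigeon")
#' @export
paradigmPreset <- function(species = c("pigeon", "human")) {
  species <- match.arg(species)
  if (species == "pigeon") {
    paradigmConfig("pigeon", n_trials = 400, ssd_initial = 450,
                   go_response_window = 5000, ssd_max = 5000,
                   intertrial_interval = 5000, punishment_timeout = 5000,
                   staircase_success_criterion = "inhibit_only",
                   n_sessions = 5L,
                   metadata = list(keys = c("init", "go", "change_top", "change_bottom")))
  } else {
    paradigmConfig("human", n_trials = 864, ssd_initial = 250,
                   go_response_window = 2500, ssd_max = 2500,
                   intertrial_interval = 900,
                   staircase_success_criterion = "inhibit_and_change",
                   n_sessions = 1L,
                   metadata = list(tones_hz = c(500, 900, 1300), tone_db = 74))
  }
}

setMethod("show", "ParadigmConfig", function(object) {
  cat(sprintf("ParadigmConfig (%s): %d trials x %d session(s)\n",
              object@species_variant, object@n_trials, object@n_sessions))
  cat(sprintf("  composition GO/SCD%g/SCD%g: %.0f%%/%.0f%%/%.0f%%\n",
              object@scd_values[1], object@scd_values[2],
              100 * object@fraction_go, 100 * object@fraction_scd0,
              100 * object@fraction_scd300))
  cat(sprintf("  SSD start %g ms, step %g ms, bounds [%g, %g]; criterion %s\n",
              object@ssd_initial, object@ssd_step, object@ssd_min,
              object@ssd_max, object@staircase_success_criterion))
})

# Largest-remainder apportionment of n into the given fractions; ties in
# the remainders are broken by listed order.
largestRemainder <- function(n, fractions) {
  ideal <- n * fractions
  base <- floor(ideal)
  rem <- ideal - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Build a randomized trial schedule
#'
#' Trial-type counts follow the configured fractions by largest-remainder
#' apportionment (ties broken in the order GO, SCD 0, SCD 300), the order
#' is a seeded uniform shuffle, and CHANGE targets are balanced within each
#' SC condition before shuffling. Deterministic given the seed.
#'
#' @param config A [ParadigmConfig-class].
#' @param seed Integer seed.
#' @return data.frame with columns `trial_index`, `trial_type` (`"GO"` or
#'   `"SC"`), `scd` (ms, NA for GO trials) and `change_target` (`"top"` or
#'   `"bottom"`, NA for GO trials).
#' @examples
#' sched <- buildSchedule(paradigmPreset("pigeon"), seed = 1)
#' table(sched$trial_type)  # 280 GO, 120 SC
#' @export
buildSchedule <- function(config, seed) {
  validObject(config)
  counts <- largestRemainder(config@n_trials,
                             c(config@fraction_go, config@fraction_scd0,
                               config@fraction_scd300))
  withSeed(seed, {
    half <- function(k) {
      tg <- rep(c("top", "bottom"), length.out = k + (k %% 2))
      sample(tg[seq_len(k)])
    }
    sched <- data.frame(
      trial_type = c(rep("GO", counts[1]), rep("SC", counts[2] + counts[3])),
      scd = c(rep(NA_real_, counts[1]),
              rep(config@scd_values[1], counts[2]),
              rep(config@scd_values[2], counts[3])),
      change_target = c(rep(NA_character_, counts[1]),
                        half(counts[2]), half(counts[3])),
      stringsAsFactors = FALSE)
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    sched$trial_index <- seq_len(nrow(sched))
    rownames(sched) <- NULL
    sched[, c("trial_index", "trial_type", "scd", "change_target")]
  })
}

#' Initialise a staircase from a configuration
#'
#' @param config A [ParadigmConfig-class].
#' @return A [StaircaseState-class] at `ssd_initial` with empty history.
#' @export
newStaircase <- function(config) {
  new("StaircaseState", current_ssd = config@ssd_initial,
      ssd_step = config@ssd_step, ssd_min = config@ssd_min,
      ssd_max = config@ssd_max,
      history = data.frame(trial_index = integer(), ssd = numeric(),
                           success = logical()))
}

setMethod("show", "StaircaseState", function(object) {
  cat(sprintf("StaircaseState: SSD %g ms (step %g, bounds [%g, %g]), %d SC trials\n",
              object@current_ssd, object@ssd_step, object@ssd_min,
              object@ssd_max, nrow(object@history)))
})

#' Apply one 1-up/1-down staircase step
#'
#' On a successful STOP-CHANGE trial 50 ms (one step) are added to the SSD
#' to make stopping harder next time; on a failure one step is subtracted.
#' The result is clamped to `[ssd_min, ssd_max]` and the trial appended to
#' the history with the SSD that was in force.
#'
#' @param state A [StaircaseState-class].
#' @param success Logical: was the SC trial successful under the session's
#'   criterion?
#' @param trial_index Optional trial index recorded in the history.
#' @return The updated [StaircaseState-class].
#' @examples
#' st <- newStaircase(paradigmPreset("pigeon"))
#' staircaseUpdate(st, TRUE)@current_ssd   # 500
#' staircaseUpdate(st, FALSE)@current_ssd  # 400
#' @export
staircaseUpdate <- function(state, success, trial_index = NA_integer_) {
  stopifnot(is(state, "StaircaseState"), is.logical(success), !is.na(success))
  used <- state@current_ssd
  nxt <- used + if (success) state@ssd_step else -state@ssd_step
  state@current_ssd <- min(max(nxt, state@ssd_min), state@ssd_max)
  state@history <- rbind(state@history,
                         data.frame(trial_index = as.integer(trial_index),
                                    ssd = used, success = success))
  state
}

#' Classify the outcome of a STOP-CHANGE trial
#'
#' Under `"inhibit_only"` the trial succeeds iff no GO response was emitted
#' after STOP onset; under `"inhibit_and_change"` a correct CHANGE response
#' within the response window (measured from CHANGE onset) is additionally
#' required. Calling this on a GO trial is a usage error.
#'
#' @param trial_type `"GO"` or `"SC"`.
#' @param go_rt GO RT in ms, or NA if the GO response was withheld.
#' @param rt2 CHANGE RT in ms (from CHANGE onset), or NA.
#' @param change_correct Logical: correct CHANGE key, NA if no CHANGE
#'   response.
#' @param criterion `"inhibit_only"` or `"inhibit_and_change"`.
#' @param go_response_window Response window in ms.
#' @return Logical success flag.
#' @export
classifyScOutcome <- function(trial_type, go_rt, rt2, change_correct,
                              criterion = c("inhibit_only", "inhibit_and_change"),
                              go_response_window = Inf) {
  criterion <- match.arg(criterion)
  if (trial_type != "SC")
    stop("classifyScOutcome() applies to SC trials only")
  inhibited <- is.na(go_rt)
  if (criterion == "inhibit_only") return(inhibited)
  inhibited && isTRUE(change_correct) && !is.na(rt2) &&
    rt2 <= go_response_window
}

#' Run one session of the paradigm against an agent
#'
#' Builds a schedule, simulates every trial with the agent, applies the
#' staircase after each SC trial (the SSD logged for a trial is the SSD in
#' force when the trial ran) and returns the tidy trial log together with
#' the final staircase state, which can be passed to the next session.
#'
#' @param agent A [RaceAgent-class].
#' @param config A [ParadigmConfig-class].
#' @param seed Integer seed for the schedule and the agent's randomness.
#' @param staircase Optional [StaircaseState-class] carried over from a
#'   previous session; defaults to a fresh one at `ssd_initial`.
#' @param session_id Integer session label written into the log.
#' @return A list with `records` (data.frame: `session_id`, `trial_index`,
#'   `trial_type`, `scd`, `ssd`, `go_rt`, `rt2`, `change_correct`,
#'   `sc_success`) and `staircase` (final [StaircaseState-class]).
#' @export
runSession <- function(agent, config, seed, staircase = NULL, session_id = 1L) {
  validObject(agent); validObject(config)
  sched <- buildSchedule(config, seed)
  if (is.null(staircase)) staircase <- newStaircase(config)
  n <- nrow(sched)
  ssd <- go_rt <- rt2 <- rep(NA_real_, n)
  change_correct <- rep(NA, n)
  sc_success <- rep(NA, n)
  withSeed(seed + 1L, {
    for (i in seq_len(n)) {
      if (sched$trial_type[i] == "GO") {
        r <- simulateTrial(agent, "GO",
                           go_response_window = config@go_response_window)
        go_rt[i] <- r$go_rt
      } else {
        ssd[i] <- staircase@current_ssd
        r <- simulateTrial(agent, "SC", scd = sched$scd[i], ssd = ssd[i],
                           go_response_window = config@go_response_window)
        if (!is.na(r$go_rt) && r$go_rt < 0) stop("agent returned a negative RT")
        go_rt[i] <- r$go_rt; rt2[i] <- r$rt2
        change_correct[i] <- r$change_correct
        sc_success[i] <- classifyScOutcome(
          "SC", r$go_rt, r$rt2, r$change_correct,
          criterion = config@staircase_success_criterion,
          go_response_window = config@go_response_window)
        staircase <- staircaseUpdate(staircase, sc_success[i],
                                     trial_index = sched$trial_index[i])
      }
    }
  })
  records <- data.frame(session_id = as.integer(session_id),
                        trial_index = sched$trial_index,
                        trial_type = sched$trial_type, scd = sched$scd,
                        ssd = ssd, go_rt = go_rt, rt2 = rt2,
                        change_correct = change_correct,
                        sc_success = sc_success, stringsAsFactors = FALSE)
  list(records = records, staircase = staircase)
}

#' Run all sessions for one subject
#'
#' Runs `config@n_sessions` sessions, carrying the staircase state across
#' sessions, and concatenates the logs (pigeon protocol: five sessions
#' pooled for analysis). Per-session seeds are fanned out from `seed`.
#'
#' @inheritParams runSession
#' @return Same shape as [runSession()], with `records` covering all
#'   sessions.
#' @export
runSubject <- function(agent, config, seed) {
  seeds <- fanOutSeeds(seed, config@n_sessions)
  staircase <- NULL
  logs <- vector("list", config@n_sessions)
  for (s in seq_len(config@n_sessions)) {
    out <- runSession(agent, config, seeds[s], staircase = staircase,
                      session_id = s)
    logs[[s]] <- out$records
    staircase <- out$staircase
  }
  list(records = do.call(rbind, logs), staircase = staircase)
}
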