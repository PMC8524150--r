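## Generative race-model agents: the synthetic-data source for behavior.

agentParamNames <- function() {
  c("go_mu", "go_sigma", "go_tau", "stop_mean", "stop_sd",
    "change_mu", "change_sigma", "change_tau",
    "d_mean", "d_sd", "rt2_noise_sd", "change_error_rate")
}

#' Construct a race-model agent
#'
#' Defaults are the pigeon-scale parameters used throughout the package
#' examples: ex-Gaussian GO RT with mean `go_mu + go_tau` = 826 ms, stopping
#' latency 216 ms, base CHANGE RT with mean 975 ms and residual interference
#' delay D = 165 ms (implying an SCD-RT2 slope of -0.55).
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian GO RT parameters (ms).
#' @param stop_mean,stop_sd Stopping latency (ms), normal truncated at 0.
#' @param change_mu,change_sigma,change_tau Ex-Gaussian base CHANGE RT (ms).
#' @param d_mean,d_sd Residual interference delay D (ms).
#' @param rt2_noise_sd Additive RT2 noise SD (ms).
#' @param change_error_rate Probability of a wrong CHANGE key.
#' @return A [RaceAgent-class] object.
#' @examples
#' a <- raceAgent(d_mean = 150)
#' expectedSlope(a)  # -0.5
#' @export
raceAgent <- function(go_mu = 746, go_sigma = 80, go_tau = 80,
                      stop_mean = 216, stop_sd = 45,
                      change_mu = 895, change_sigma = 80, change_tau = 80,
                      d_mean = 165, d_sd = 0,
                      rt2_noise_sd = 80, change_error_rate = 0.05) {
  new("RaceAgent",
      go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
      stop_mean = stop_mean, stop_sd = stop_sd,
      change_mu = change_mu, change_sigma = change_sigma,
      change_tau = change_tau,
      d_mean = d_mean, d_sd = d_sd,
      rt2_noise_sd = rt2_noise_sd, change_error_rate = change_error_rate)
}

setMethod("show", "RaceAgent", function(object) {
  cat("RaceAgent\n")
  cat(sprintf("  GO RT      ex-Gaussian(mu=%g, sigma=%g, tau=%g), mean %g ms\n",
              object@go_mu, object@go_sigma, object@go_tau,
              object@go_mu + object@go_tau))
  cat(sprintf("  stop       Normal(%g, %g) ms\n", object@stop_mean, object@stop_sd))
  cat(sprintf("  change     ex-Gaussian(mu=%g, sigma=%g, tau=%g) ms\n",
              object@change_mu, object@change_sigma, object@change_tau))
  cat(sprintf("  D          %g ms (sd %g); expected slope %.3f\n",
              object@d_mean, object@d_sd, expectedSlope(object)))
  cat(sprintf("  RT2 noise  %g ms; change error rate %g\n",
              object@rt2_noise_sd, object@change_error_rate))
})

#' Simulate one trial of the STOP-CHANGE paradigm
#'
#' Applies the independent race rule. On a GO trial the ex-Gaussian GO RT is
#' sampled and an omission logged if it exceeds the response window. On a
#' STOP-CHANGE (SC) trial the GO response is emitted iff the sampled GO RT
#' beats `ssd + stop latency`; when the GO response is withheld, the CHANGE
#' response time (RT2, from CHANGE onset) is
#' `max(0, D - scd) + base CHANGE RT + noise`, and the CHANGE key is wrong
#' with probability `change_error_rate`.
#'
#' @param agent A [RaceAgent-class].
#' @param trial_type `"GO"` or `"SC"`.
#' @param scd STOP-CHANGE delay in ms (SC trials).
#' @param ssd Stop-signal delay in ms (SC trials).
#' @param go_response_window Response deadline in ms.
#' @return A list with `go_rt` (NA if no GO response was emitted), `rt2`
#'   (NA unless the GO response was withheld on an SC trial) and
#'   `change_correct` (logical, NA for GO trials).
#' @export
simulateTrial <- function(agent, trial_type, scd = NA_real_, ssd = NA_real_,
                          go_response_window = Inf) {
  go <- rexgauss(1L, agent@go_mu, agent@go_sigma, agent@go_tau)
  if (trial_type == "GO") {
    return(list(go_rt = if (go <= go_response_window) go else NA_real_,
                rt2 = NA_real_, change_correct = NA))
  }
  stopifnot(is.finite(ssd), is.finite(scd))
  stop_lat <- rnormPos(1L, agent@stop_mean, agent@stop_sd)
  emitted <- go < ssd + stop_lat && go <= go_response_window
  if (emitted) {
    return(list(go_rt = go, rt2 = NA_real_, change_correct = NA))
  }
  d <- if (agent@d_sd > 0) max(0, rnorm(1L, agent@d_mean, agent@d_sd)) else agent@d_mean
  base <- rexgauss(1L, agent@change_mu, agent@change_sigma, agent@change_tau)
  noise <- if (agent@rt2_noise_sd > 0) rnorm(1L, 0, agent@rt2_noise_sd) else 0
  rt2 <- max(0, max(0, d - scd) + base + noise)
  list(go_rt = NA_real_, rt2 = rt2,
       change_correct = runif(1L) >= agent@change_error_rate)
}

#' Expected SCD-RT2 slope of an agent
#'
#' Closed form of the slope implied by the interference-delay model for SCD
#' values 0 and 300 ms:
#' `-(E[max(0, D)] - E[max(0, D - 300)]) / 300` with
#' `D = max(0, Normal(d_mean, d_sd))`. For a deterministic D in \[0, 300\]
#' this reduces to `-D/300`; the value is always within \[-1, 0\].
#'
#' @param agent A [RaceAgent-class].
#' @param scd_values Length-2 ascending SCD values in ms.
#' @return Dimensionless slope in \[-1, 0\].
#' @export
expectedSlope <- function(agent, scd_values = c(0, 300)) {
  stopifnot(length(scd_values) == 2, scd_values[2] > scd_values[1])
  e0 <- expectedPositivePart(agent@d_mean, agent@d_sd, scd_values[1])
  e1 <- expectedPositivePart(agent@d_mean, agent@d_sd, scd_values[2])
  -(e0 - e1) / (scd_values[2] - scd_values[1])
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param means,sds Named numeric vectors of population means and
#'   between-subject SDs; names must cover every [RaceAgent-class]
#'   parameter. Unnamed entries are an error.
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @seealso [pigeonCohortSpec()], [humanCohortSpec()], [makeCohort()]
#' @export
cohortSpec <- function(n_subjects, means, sds, seed = 1L) {
  new("CohortSpec", n_subjects = as.integer(n_subjects),
      means = means[agentParamNames()], sds = sds[agentParamNames()],
      seed = as.integer(seed))
}

defaultCohortSds <- function(go_mu_sd, stop_sd, change_mu_sd, d_sd) {
  c(go_mu = go_mu_sd, go_sigma = 0, go_tau = 0,
    stop_mean = stop_sd, stop_sd = 0,
    change_mu = change_mu_sd, change_sigma = 0, change_tau = 0,
    d_mean = d_sd, d_sd = 0, rt2_noise_sd = 0, change_error_rate = 0)
}

#' Shipped cohort presets
#'
#' Population parameters chosen so that simulated cohorts reproduce the
#' group means and SEMs of the reference behavioral data: pigeons with mean
#' GO RT 826 ms, stopping latency 216 ms, base CHANGE RT 975 ms and D = 165
#' ms (slope -0.55); humans with mean GO RT 507 ms, stopping latency 240
#' ms, base CHANGE RT 693 ms and D = 161 ms (slope -0.54). Between-subject
#' SDs equal the printed SEMs times sqrt(20).
#'
#' @param n_subjects Cohort size (default 20).
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @export
pigeonCohortSpec <- function(n_subjects = 20, seed = 1L) {
  cohortSpec(n_subjects,
    means = c(go_mu = 746, go_sigma = 80, go_tau = 80,
              stop_mean = 216, stop_sd = 45,
              change_mu = 895, change_sigma = 80, change_tau = 80,
              d_mean = 165, d_sd = 0, rt2_noise_sd = 80,
              change_error_rate = 0.05),
    sds = defaultCohortSds(215, 45, 161, 80),
    seed = seed)
}

#' @rdname pigeonCohortSpec
#' @export
humanCohortSpec <- function(n_subjects = 20, seed = 1L) {
  cohortSpec(n_subjects,
    means = c(go_mu = 427, go_sigma = 60, go_tau = 80,
              stop_mean = 240, stop_sd = 40,
              change_mu = 613, change_sigma = 60, change_tau = 80,
              d_mean = 161, d_sd = 0, rt2_noise_sd = 60,
              change_error_rate = 0.05),
    sds = defaultCohortSds(107, 45, 170, 67),
    seed = seed)
}

#' Draw a cohort of agents
#'
#' Per-subject parameters are drawn independently from
#' `Normal(mean, sd)` truncated at zero (the error rate is additionally
#' capped below 1); `sd = 0` copies the population mean. Deterministic
#' given the spec's seed.
#'
#' @param spec A [CohortSpec-class].
#' @return A list of [RaceAgent-class] objects named `S01`, `S02`, ...
#' @export
makeCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    agents <- lapply(seq_len(spec@n_subjects), function(i) {
      p <- vapply(agentParamNames(), function(nm)
        rnormPos(1L, spec@means[[nm]], spec@sds[[nm]]), numeric(1))
      p[["change_error_rate"]] <- min(p[["change_error_rate"]], 0.99)
      do.call(raceAgent, as.list(p))
    })
    names(agents) <- sprintf("S%02d", seq_len(spec@n_subjects))
    agents
  })
}
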