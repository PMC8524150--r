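#' @import methods
NULL

#' Paradigm configuration for a STOP-CHANGE session
#'
#' Holds every tunable of one species variant of the STOP-CHANGE task: trial
#' composition, stop-signal-delay (SSD) staircase settings, response window
#' and timing constants. Use [paradigmPreset()] for the two shipped presets
#' (pigeon: 400 trials per session over 5 sessions, SSD starting at 450 ms;
#' human: 864 trials in one session).
#'
#' @slot species_variant `"pigeon"` or `"human"`.
#' @slot n_trials Trials per session.
#' @slot fraction_go,fraction_scd0,fraction_scd300 Trial-type proportions;
#'   must sum to 1.
#' @slot scd_values STOP-CHANGE delays in ms, ascending (default `c(0, 300)`).
#' @slot ssd_initial,ssd_step,ssd_min,ssd_max Staircase start, step (50 ms)
#'   and clamping bounds in ms.
#' @slot go_response_window Response deadline in ms, from GO onset.
#' @slot intertrial_interval,punishment_timeout Timing constants in ms
#'   (carried for provenance; the simulator does not wait).
#' @slot staircase_success_criterion `"inhibit_only"` (a staircase success is
#'   a withheld GO response) or `"inhibit_and_change"` (additionally requires
#'   a correct CHANGE response within the window).
#' @slot n_sessions Number of sessions run per subject; the staircase state
#'   carries across sessions and the logs are pooled.
#' @slot metadata Free-form list (tone frequencies, key layout); carried, not
#'   interpreted.
#' @seealso [paradigmPreset()], [buildSchedule()], [runSession()]
#' @export
setClass("ParadigmConfig",
  representation(
    species_variant = "character",
    n_trials = "integer",
    fraction_go = "numeric",
    fraction_scd0 = "numeric",
    fraction_scd300 = "numeric",
    scd_values = "numeric",
    ssd_initial = "numeric",
    ssd_step = "numeric",
    ssd_min = "numeric",
    ssd_max = "numeric",
    go_response_window = "numeric",
    intertrial_interval = "numeric",
    punishment_timeout = "numeric",
    staircase_success_criterion = "character",
    n_sessions = "integer",
    metadata = "list"
  )
)

setValidity("ParadigmConfig", function(object) {
  msgs <- character()
  if (!object@species_variant %in% c("pigeon", "human"))
    msgs <- c(msgs, "species_variant must be 'pigeon' or 'human'")
  fr <- c(object@fraction_go, object@fraction_scd0, object@fraction_scd300)
  if (any(fr < 0)) msgs <- c(msgs, "trial fractions must be nonnegative")
  if (abs(sum(fr) - 1) > 1e-8)
    msgs <- c(msgs, "fraction_go + fraction_scd0 + fraction_scd300 must equal 1")
  if (object@n_trials < 1L) msgs <- c(msgs, "n_trials must be >= 1")
  if (object@ssd_step <= 0) msgs <- c(msgs, "ssd_step must be > 0")
  if (!(object@ssd_min <= object@ssd_initial && object@ssd_initial <= object@ssd_max))
    msgs <- c(msgs, "need ssd_min <= ssd_initial <= ssd_max")
  if (is.unsorted(object@scd_values, strictly = TRUE))
    msgs <- c(msgs, "scd_values must be strictly ascending")
  if (!object@staircase_success_criterion %in% c("inhibit_only", "inhibit_and_change"))
    msgs <- c(msgs, "unknown staircase_success_criterion")
  if (object@n_sessions < 1L) msgs <- c(msgs, "n_sessions must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' State of the 1-up/1-down SSD staircase
#'
#' Tracks the current stop-signal delay and the full adjustment history.
#' After every STOP-CHANGE trial the SSD moves up one step on success
#' (stopping is made harder) and down one step on failure, clamped to
#' `[ssd_min, ssd_max]`, so the success probability converges to 50%.
#'
#' @slot current_ssd Current SSD in ms.
#' @slot ssd_step,ssd_min,ssd_max Step size and clamping bounds in ms.
#' @slot history data.frame with columns `trial_index`, `ssd` (the SSD used
#'   on that trial), `success`.
#' @seealso [newStaircase()], [staircaseUpdate()]
#' @export
setClass("StaircaseState",
  representation(
    current_ssd = "numeric",
    ssd_step = "numeric",
    ssd_min = "numeric",
    ssd_max = "numeric",
    history = "data.frame"
  )
)

setValidity("StaircaseState", function(object) {
  msgs <- character()
  if (object@current_ssd < object@ssd_min - 1e-9 ||
      object@current_ssd > object@ssd_max + 1e-9)
    msgs <- c(msgs, "current_ssd outside [ssd_min, ssd_max]")
  if (object@ssd_step <= 0) msgs <- c(msgs, "ssd_step must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Generative race-model agent
#'
#' Parameters of the synthetic subject used to simulate STOP-CHANGE
#' behavior. GO reaction times are ex-Gaussian; the covert stopping latency
#' is normal (truncated at 0) and races the GO process independently: the GO
#' response is emitted iff GO RT < SSD + stop latency. When the GO response
#' is inhibited, the CHANGE response time measured from CHANGE onset is
#' `max(0, D - SCD) + change base RT + noise`, where the residual
#' interference delay `D` (slot `d_mean`, ms) is the serial-to-parallel
#' knob: `D = 0` gives a flat SCD-RT2 function (slope 0, fully serial),
#' `D >= 300` gives slope -1 (fully parallel).
#'
#' @slot go_mu,go_sigma,go_tau Ex-Gaussian GO RT parameters (ms).
#' @slot stop_mean,stop_sd Stopping-latency distribution (ms).
#' @slot change_mu,change_sigma,change_tau Ex-Gaussian base CHANGE RT (ms).
#' @slot d_mean,d_sd Residual interference delay D (ms): per-trial
#'   `D = max(0, Normal(d_mean, d_sd))`; `d_sd = 0` makes D a subject
#'   constant.
#' @slot rt2_noise_sd Additive RT2 noise (ms).
#' @slot change_error_rate Probability a CHANGE response hits the wrong key.
#' @seealso [raceAgent()], [expectedSlope()], [simulateTrial()]
#' @export
setClass("RaceAgent",
  representation(
    go_mu = "numeric", go_sigma = "numeric", go_tau = "numeric",
    stop_mean = "numeric", stop_sd = "numeric",
    change_mu = "numeric", change_sigma = "numeric", change_tau = "numeric",
    d_mean = "numeric", d_sd = "numeric",
    rt2_noise_sd = "numeric",
    change_error_rate = "numeric"
  )
)

setValidity("RaceAgent", function(object) {
  msgs <- character()
  num <- c(object@go_mu, object@go_sigma, object@go_tau, object@stop_mean,
           object@stop_sd, object@change_mu, object@change_sigma,
           object@change_tau, object@d_mean, object@d_sd, object@rt2_noise_sd)
  if (any(!is.finite(num)) || any(num < 0))
    msgs <- c(msgs, "all time parameters must be finite and >= 0")
  if (object@change_error_rate < 0 || object@change_error_rate >= 1)
    msgs <- c(msgs, "change_error_rate must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Population specification for a synthetic cohort
#'
#' Population-level means and between-subject standard deviations for every
#' [RaceAgent-class] parameter; [makeCohort()] draws per-subject parameters
#' from normal distributions truncated at zero.
#'
#' @slot n_subjects Number of subjects.
#' @slot means,sds Named numeric vectors over the RaceAgent parameter names.
#' @slot seed Integer seed making the cohort reproducible.
#' @seealso [cohortSpec()], [makeCohort()], [pigeonCohortSpec()],
#'   [humanCohortSpec()]
#' @export
setClass("CohortSpec",
  representation(
    n_subjects = "integer",
    means = "numeric",
    sds = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@n_subjects < 1L) msgs <- c(msgs, "n_subjects must be >= 1")
  if (any(object@sds < 0)) msgs <- c(msgs, "between-subject SDs must be >= 0")
  need <- agentParamNames()
  if (!all(need %in% names(object@means)) || !all(need %in% names(object@sds)))
    msgs <- c(msgs, "means and sds must be named over all RaceAgent parameters")
  if (length(msgs)) msgs else TRUE
})

#' Grayscale section micrograph with region of interest
#'
#' An 8-bit grayscale image of a stained brain section (dark cells on a
#' light background), its delineated region of interest, anatomical
#' annotations and, for synthetic sections, the exact ground truth of the
#' planted cells. Pixel coordinates are 0-based with the half-open raster
#' convention: matrix cell `[r, c]` covers `[c-1, c) x [r-1, r)` and has
#' center `(c - 0.5, r - 0.5)`.
#'
#' @slot pixels Integer matrix (rows = y), values 0-255.
#' @slot pixel_size Pixel edge length in mm.
#' @slot roi Closed simple polygon, n x 2 matrix of (x, y) pixel coordinates.
#' @slot area_label One of `"CPi"`, `"NMm"`, `"NIML"`, `"MM"` (or any label).
#' @slot hemisphere `"left"` or `"right"`.
#' @slot slice_position Anterior coordinate in mm.
#' @slot subject_id Subject identifier.
#' @slot ground_truth data.frame of planted cells (columns `x`, `y`, `a`,
#'   `b`, `theta`, `peak`), or a 0-row data.frame for real images.
#' @seealso [generateSyntheticSection()], [countParticles()],
#'   [readSectionImage()]
#' @export
setClass("SectionImage",
  representation(
    pixels = "matrix",
    pixel_size = "numeric",
    roi = "matrix",
    area_label = "character",
    hemisphere = "character",
    slice_position = "numeric",
    subject_id = "character",
    ground_truth = "data.frame"
  )
)

setValidity("SectionImage", function(object) {
  msgs <- character()
  if (object@pixel_size <= 0) msgs <- c(msgs, "pixel_size must be > 0")
  if (ncol(object@roi) != 2 || nrow(object@roi) < 3)
    msgs <- c(msgs, "roi must be an n x 2 polygon with n >= 3")
  if (any(object@pixels < 0 | object@pixels > 255))
    msgs <- c(msgs, "pixel values must be within 0..255")
  if (polygonSelfIntersects(object@roi))
    msgs <- c(msgs, "roi polygon must be simple (non-self-intersecting)")
  if (length(msgs)) msgs else TRUE
})

#' Staining-intensity threshold band
#'
#' Inclusive intensity band on the stain (inverted) channel: a pixel is
#' foreground iff `lower <= 255 - gray <= upper`. The band is calibrated
#' once from weak and intense exemplar cells in the control region and then
#' frozen for every image of the run.
#'
#' @slot lower,upper 8-bit stain intensities, `0 <= lower <= upper <= 255`.
#' @seealso [calibrateThresholds()], [countParticles()]
#' @export
setClass("ThresholdBand",
  representation(lower = "numeric", upper = "numeric")
)

setValidity("ThresholdBand", function(object) {
  if (object@lower < 0 || object@upper > 255 || object@lower > object@upper)
    "need 0 <= lower <= upper <= 255" else TRUE
})
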