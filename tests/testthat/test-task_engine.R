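test_that("schedule composition follows largest-remainder apportionment", {
  pig <- buildSchedule(paradigmPreset("pigeon"), seed = 1)
  expect_equal(sum(pig$trial_type == "GO"), 280)
  expect_equal(sum(pig$scd == 0, na.rm = TRUE), 60)
  expect_equal(sum(pig$scd == 300, na.rm = TRUE), 60)

  hum <- buildSchedule(paradigmPreset("human"), seed = 1)
  expect_equal(sum(hum$trial_type == "GO"), 605)
  # 864 * 0.15 = 129.6 for both SC cells; the tie goes to SCD 0 first
  expect_equal(sum(hum$scd == 0, na.rm = TRUE), 130)
  expect_equal(sum(hum$scd == 300, na.rm = TRUE), 129)

  # property: per-type count never deviates from the ideal by more than 1
  cfg <- paradigmPreset("pigeon")
  for (n in c(7L, 13L, 101L, 399L, 864L)) {
    cfg@n_trials <- n
    s <- buildSchedule(cfg, seed = n)
    counts <- c(sum(s$trial_type == "GO"),
                sum(s$scd == 0, na.rm = TRUE),
                sum(s$scd == 300, na.rm = TRUE))
    expect_true(all(abs(counts - n * c(0.70, 0.15, 0.15)) < 1))
    expect_equal(sum(counts), n)
  }
})

test_that("schedules are deterministic given the seed and balance targets", {
  cfg <- paradigmPreset("human")
  expect_identical(buildSchedule(cfg, 7), buildSchedule(cfg, 7))
  expect_false(identical(buildSchedule(cfg, 7), buildSchedule(cfg, 8)))
  s <- buildSchedule(cfg, 7)
  tg <- table(s$change_target[s$scd == 0])
  expect_equal(unname(abs(tg[1] - tg[2])), 0)  # 130 targets split 65/65
})

test_that("staircase moves one step per SC outcome and clamps at bounds", {
  st <- newStaircase(paradigmPreset("pigeon"))
  expect_equal(staircaseUpdate(st, TRUE)@current_ssd, 500)
  expect_equal(staircaseUpdate(st, FALSE)@current_ssd, 400)
  low <- st; low@current_ssd <- 0
  expect_equal(staircaseUpdate(low, FALSE)@current_ssd, 0)

  # trace property over a simulated run
  out <- runSession(raceAgent(), scOnlyConfig(300), seed = 3)
  trace <- out$staircase@history$ssd
  expect_true(all(trace >= 0 & trace <= 5000))
  expect_true(all(abs(diff(trace)) %in% c(0, 50)))
})

test_that("SC outcomes are classified by criterion and GO trials rejected", {
  expect_true(classifyScOutcome("SC", NA, 600, TRUE, "inhibit_and_change"))
  expect_false(classifyScOutcome("SC", NA, 600, FALSE, "inhibit_and_change"))
  expect_true(classifyScOutcome("SC", NA, 600, FALSE, "inhibit_only"))
  expect_false(classifyScOutcome("SC", 480, NA, NA, "inhibit_only"))
  expect_false(classifyScOutcome("SC", 480, NA, NA, "inhibit_and_change"))
  # a late CHANGE response fails the stricter criterion
  expect_false(classifyScOutcome("SC", NA, 2600, TRUE, "inhibit_and_change",
                                 go_response_window = 2500))
  expect_error(classifyScOutcome("GO", 500, NA, NA), "SC trials only")
})

test_that("an agent that never inhibits drives the SSD to its floor", {
  never <- fixedAgent(go = 100, stop = 5000)  # GO always wins the race
  out <- runSession(never, scOnlyConfig(120, ssd_initial = 200), seed = 1)
  expect_false(any(out$records$sc_success))
  expect_equal(out$staircase@current_ssd, 0)
  expect_true(all(tail(out$records$ssd, 50) == 0))
})

test_that("a deterministic agent settles into the two-state oscillation", {
  # success iff SSD <= 600 (800 >= ssd + 200): the staircase must end up
  # alternating between 600 and 650
  out <- runSession(fixedAgent(), scOnlyConfig(200), seed = 1)
  late <- tail(out$records$ssd, 60)
  expect_setequal(unique(late), c(600, 650))
  expect_true(all(abs(diff(late)) == 50))
})

test_that("the staircase holds a stochastic race agent near 50% success", {
  out <- runSession(raceAgent(), scOnlyConfig(400), seed = 9)
  expect_gt(mean(out$records$sc_success), 0.40)
  expect_lt(mean(out$records$sc_success), 0.60)
})

test_that("multi-session subjects carry the staircase across sessions", {
  cfg <- paradigmPreset("pigeon")
  cfg@n_trials <- 60L; cfg@n_sessions <- 3L
  log <- runSubject(raceAgent(), cfg, seed = 4)
  expect_equal(unique(log$records$session_id), 1:3)
  s2 <- log$records[log$records$session_id == 2 & log$records$trial_type == "SC", ]
  s1 <- log$records[log$records$session_id == 1 & log$records$trial_type == "SC", ]
  # session 2 starts where session 1 left off, not back at ssd_initial
  last1 <- tail(s1, 1)
  expected_start <- last1$ssd + ifelse(last1$sc_success, 50, -50)
  expect_equal(s2$ssd[1], max(min(expected_start, 5000), 0))
})

test_that("invalid configurations are rejected", {
  expect_error(paradigmConfig("pigeon", 100, fraction_go = 0.5,
                              fraction_scd0 = 0.2, fraction_scd300 = 0.2,
                              ssd_initial = 450, go_response_window = 5000,
                              intertrial_interval = 5000,
                              staircase_success_criterion = "inhibit_only"),
               "must equal 1")
  expect_error(paradigmConfig("pigeon", 100, ssd_initial = -10,
                              go_response_window = 5000,
                              intertrial_interval = 5000,
                              staircase_success_criterion = "inhibit_only"),
               "ssd_min <= ssd_initial")
})
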