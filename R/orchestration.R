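## Orchestration: trial-log I/O and the full synthetic reproduction of the
## behavioral and histology experiments.

# Rolling polynomial hash of a character scalar; provenance fingerprint
# for configs (not cryptographic).
rollingHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

configHash <- function(config) {
  rollingHash(paste(deparse(lapply(slotNames(config), function(s) slot(config, s))),
                    collapse = ""))
}

#' Write and read tidy trial logs
#'
#' One row per trial; absent values are written as `NA`; numeric columns
#' are serialised with 17 significant digits so logs round-trip
#' losslessly. Header comment lines (`#`) carry the config hash and seed.
#'
#' @param records Trial log data.frame (see [runSession()]).
#' @param path CSV file path.
#' @param seed Seed recorded in the header.
#' @param config Optional [ParadigmConfig-class] whose hash is recorded.
#' @return `writeTrialLog()` returns `path` invisibly; `readTrialLog()`
#'   returns the data.frame with a `header` attribute of the comment
#'   lines.
#' @export
writeTrialLog <- function(records, path, seed = NA, config = NULL) {
  hdr <- c("# stopchange trial log",
           sprintf("# seed: %s", seed),
           if (!is.null(config)) sprintf("# config_hash: %s", configHash(config)))
  fmt <- records
  for (j in seq_along(fmt)) {
    fmt[[j]] <- if (is.double(fmt[[j]])) sprintf("%.17g", fmt[[j]])
                else as.character(fmt[[j]])
    fmt[[j]][is.na(records[[j]])] <- "NA"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.csv(text = lines[!startsWith(lines, "#")],
                 stringsAsFactors = FALSE)
  for (nm in c("scd", "ssd", "go_rt", "rt2"))
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("change_correct", "sc_success"))
    if (nm %in% names(df)) df[[nm]] <- as.logical(df[[nm]])
  attr(df, "header") <- hdr
  df
}

#' Simulate and analyse the cross-species behavioral experiment
#'
#' Runs the full behavioral comparison on synthetic cohorts: simulates a
#' pigeon and a human cohort through their paradigm presets, summarises
#' every subject, and computes the four Bonferroni-corrected
#' between-species t-tests (GO RT, SSD, SSRT, slope; family alpha
#' 0.05/4 = 0.0125), the 2 x 2 condition-by-species mixed ANOVA on the
#' SC reaction times and the BIC-approximate Bayes factor for the absent
#' interaction. Deterministic given `seed`.
#'
#' @param seed Master seed; per-subject seeds are fanned out from it.
#' @param pigeon_spec,human_spec [CohortSpec-class] objects (the cohort
#'   seeds are overwritten from the master seed).
#' @param pigeon_config,human_config [ParadigmConfig-class] presets.
#' @param ssd_burn_in SC trials excluded from each subject's mean SSD.
#' @param out_dir Optional directory for `subjects.csv`, `groups.csv` and
#'   `stats.json`.
#' @return List: `subjects`, `groups`, `t_tests`, `anova`, `bf01`,
#'   `alpha`, `seed`.
#' @export
runBehaviorExperiment <- function(seed,
                                  pigeon_spec = pigeonCohortSpec(),
                                  human_spec = humanCohortSpec(),
                                  pigeon_config = paradigmPreset("pigeon"),
                                  human_config = paradigmPreset("human"),
                                  ssd_burn_in = 20, out_dir = NULL) {
  seeds <- fanOutSeeds(seed, 2L + pigeon_spec@n_subjects + human_spec@n_subjects)
  pigeon_spec@seed <- seeds[1]; human_spec@seed <- seeds[2]
  subj_seeds <- seeds[-(1:2)]

  simulateCohort <- function(spec, config, species, seed_offset) {
    agents <- makeCohort(spec)
    do.call(rbind, lapply(seq_along(agents), function(i) {
      log <- runSubject(agents[[i]], config, subj_seeds[seed_offset + i])
      summarizeSubject(log$records,
                       subject_id = sprintf("%s_%02d", species, i),
                       group = "STOP-CHANGE", species = species,
                       ssd_burn_in = ssd_burn_in)
    }))
  }
  subjects <- rbind(
    simulateCohort(pigeon_spec, pigeon_config, "pigeon", 0L),
    simulateCohort(human_spec, human_config, "human", pigeon_spec@n_subjects))
  groups <- summarizeGroup(subjects, by = "species")

  sp <- split(subjects, subjects$species)
  t_tests <- lapply(c(go_rt = "mean_go_rt", ssd = "mean_ssd",
                      ssrt = "ssrt", slope = "slope"),
                    function(m) tTest(sp$pigeon[[m]], sp$human[[m]], "student"))

  long <- rbind(
    data.frame(subject = subjects$subject_id, species = subjects$species,
               condition = "SCD0", rt2 = subjects$mean_rt2_scd0),
    data.frame(subject = subjects$subject_id, species = subjects$species,
               condition = "SCD300", rt2 = subjects$mean_rt2_scd300))
  anova <- mixedAnova(long, "rt2", "subject", "condition", "species")
  bf <- interactionBF01(long, "rt2", "subject", "condition", "species")

  res <- list(subjects = subjects, groups = groups, t_tests = t_tests,
              anova = anova, bf01 = bf,
              alpha = bonferroniAlpha(0.05, 4), seed = seed)
  if (!is.null(out_dir)) writeBehaviorOutputs(res, out_dir)
  res
}

writeBehaviorOutputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeCsv17 <- function(df, path) {
    for (j in seq_along(df)) if (is.double(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  writeCsv17(res$subjects, file.path(out_dir, "subjects.csv"))
  writeCsv17(res$groups, file.path(out_dir, "groups.csv"))
  stats <- list(
    seed = res$seed, alpha_bonferroni = res$alpha,
    t_tests = lapply(res$t_tests, function(t)
      t[c("statistic", "df", "p.value", "mean_diff", "variant")]),
    anova = res$anova$effects, anova_ss = res$anova$ss,
    bf01_interaction = res$bf01$bf01)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

# Printed group means (cells/mm^2) and SEMs of the reference histology
# data; between-subject SDs are SEM * sqrt(n). Used as planting targets
# for the synthetic histology generator.
zenkAreaTable <- function() {
  data.frame(
    area = rep(c("CPi", "NMm", "NIML", "MM"), each = 3),
    group = rep(c("GO", "STOP", "STOP-CHANGE"), 4),
    mean = c(870, 737, 836, 273, 482, 1137, 917, 1912, 1739, 497, 931, 1421),
    sem = c(134, 148, 206, 130, 145, 206, 290, 161, 168, 231, 166, 205),
    n = rep(c(6, 6, 8), 4))
}

#' Simulate and analyse the histology (ZENK) experiment
#'
#' Generates synthetic stained sections for three pigeon groups (GO, STOP,
#' STOP-CHANGE) in four areas (control region CPi plus NMm, NIML, MM), two
#' hemispheres and the protocol slice counts (2 for CPi, 3 elsewhere);
#' counts particles with a band calibrated once from the CPi control
#' sections; standardises to cells per mm^2 and aggregates slices and
#' hemispheres. It then runs the hemisphere checks (pooling iff
#' non-significant), the area-by-group mixed ANOVA with Bonferroni
#' pairwise comparisons, and - for the STOP-CHANGE group, whose behavior
#' is simulated per subject - the three Spearman correlations between the
#' SCD-RT2 slope and area activity at alpha 0.05/3 = 0.0167. In the
#' generator, each STOP-CHANGE subject's NIML density is coupled to its
#' slope (`niml_slope_gain` cells/mm^2 per slope unit), emulating the
#' reference finding that more serial subjects show higher NIML activity.
#' Deterministic given `seed`.
#'
#' @param seed Master seed.
#' @param group_sizes Named sizes for GO, STOP and STOP-CHANGE groups.
#' @param density_scale Multiplier on all planted densities (scaled-down
#'   runs for quick checks).
#' @param width,height,pixel_size,margin Synthetic section geometry.
#' @param niml_slope_gain Slope-to-NIML-density coupling (cells/mm^2).
#' @param behavior_config Paradigm for the STOP-CHANGE group's final
#'   session (default: one 400-trial pigeon session).
#' @param out_dir Optional directory for `densities.csv`,
#'   `densities_aggregated.csv` and `stats.json`.
#' @return List: `slice_densities`, `densities` (aggregated),
#'   `hemisphere_tests`, `pooled`, `anova`, `pairwise`, `correlations`,
#'   `slopes`, `band`, `alpha_correlations`, `seed`.
#' @export
runZenkExperiment <- function(seed,
                              group_sizes = c(GO = 6, STOP = 6, `STOP-CHANGE` = 8),
                              density_scale = 1,
                              width = 192, height = 192,
                              pixel_size = 0.001, margin = 8,
                              niml_slope_gain = 1500,
                              behavior_config = NULL,
                              out_dir = NULL) {
  tab <- zenkAreaTable()
  groups <- rep(names(group_sizes), group_sizes)
  n_subj <- length(groups)
  seeds <- fanOutSeeds(seed, 3L)
  if (is.null(behavior_config)) {
    behavior_config <- paradigmPreset("pigeon")
    behavior_config@n_sessions <- 1L
  }

  # STOP-CHANGE behavior: one final session per subject, slope per subject.
  sc_ids <- which(groups == "STOP-CHANGE")
  sc_agents <- makeCohort(pigeonCohortSpec(length(sc_ids), seed = seeds[1]))
  sc_seeds <- fanOutSeeds(seeds[1] + 1L, length(sc_ids))
  slopes <- vapply(seq_along(sc_ids), function(i) {
    log <- runSubject(sc_agents[[i]], behavior_config, sc_seeds[i])
    summarizeSubject(log$records, ssd_burn_in = 10)$slope
  }, numeric(1))
  slope_tab <- data.frame(subject_id = sprintf("Z%02d", sc_ids), slope = slopes)

  # Subject-level planted densities per area.
  roi_mm2 <- (width - 2 * margin) * (height - 2 * margin) * pixel_size^2
  areas <- c("CPi", "NMm", "NIML", "MM")
  planted <- withSeed(seeds[2], {
    do.call(rbind, lapply(seq_len(n_subj), function(i) {
      do.call(rbind, lapply(areas, function(a) {
        row <- tab[tab$area == a & tab$group == groups[i], ]
        m <- row$mean
        if (a == "NIML" && groups[i] == "STOP-CHANGE") {
          k <- match(i, sc_ids)
          resid_sd <- sqrt(max((row$sem * sqrt(row$n))^2 -
                                 (niml_slope_gain * 0.27)^2, 0))
          m <- m + niml_slope_gain * (slope_tab$slope[k] + 0.55) +
            rnorm(1, 0, resid_sd)
        } else {
          m <- rnorm(1, m, row$sem * sqrt(row$n))
        }
        data.frame(subject_id = sprintf("Z%02d", i), group = groups[i],
                   area_label = a, density = max(m, 20) * density_scale)
      }))
    }))
  })

  # Generate sections, calibrate the band on CPi, count everywhere.
  slice_plan <- c(CPi = 2L, NMm = 3L, NIML = 3L, MM = 3L)
  sec_seed <- seeds[3]
  sections <- list()
  withSeed(sec_seed, {
    for (r in seq_len(nrow(planted))) {
      a <- planted$area_label[r]
      for (hemi in c("left", "right")) {
        for (sl in seq_len(slice_plan[[a]])) {
          n_cells <- rpois(1, planted$density[r] * roi_mm2)
          sections[[length(sections) + 1L]] <- generateSyntheticSection(
            n_cells, width = width, height = height, pixel_size = pixel_size,
            margin = margin, seed = sample.int(.Machine$integer.max - 1L, 1),
            area_label = a, hemisphere = hemi, slice_position = sl,
            subject_id = planted$subject_id[r])
        }
      }
    }
  })
  is_cpi <- vapply(sections, function(s) s@area_label == "CPi", logical(1))
  band <- calibrateThresholds(sections[is_cpi])
  slice_densities <- do.call(rbind, lapply(sections, function(s) {
    parts <- countParticles(s, band)
    data.frame(subject_id = s@subject_id, area_label = s@area_label,
               hemisphere = s@hemisphere, slice = s@slice_position,
               n_particles = nrow(parts),
               cells_per_mm2 = densityPerMm2(nrow(parts), roiAreaPx(s),
                                             s@pixel_size),
               stringsAsFactors = FALSE)
  }))

  # Hemisphere effect and hemisphere-by-area interaction; pool iff both ns.
  by_hemi <- aggregateSubject(slice_densities, pool_hemispheres = FALSE)
  by_hemi$group <- groups[match(by_hemi$subject_id,
                                sprintf("Z%02d", seq_len(n_subj)))]
  subj_hemi <- aggregate(cells_per_mm2 ~ subject_id + hemisphere + group,
                         by_hemi, mean)
  hemi_main <- mixedAnova(subj_hemi, "cells_per_mm2", "subject_id",
                          "hemisphere", "group")
  hdiff <- merge(by_hemi[by_hemi$hemisphere == "left",
                         c("subject_id", "area_label", "group", "cells_per_mm2")],
                 by_hemi[by_hemi$hemisphere == "right",
                         c("subject_id", "area_label", "cells_per_mm2")],
                 by = c("subject_id", "area_label"),
                 suffixes = c("_l", "_r"))
  hdiff$diff <- hdiff$cells_per_mm2_l - hdiff$cells_per_mm2_r
  hemi_by_area <- mixedAnova(hdiff, "diff", "subject_id", "area_label", "group")
  hemisphere_tests <- list(
    main = hemi_main$effects[hemi_main$effects$effect == "within", ],
    by_area = hemi_by_area$effects[hemi_by_area$effects$effect == "within", ])
  pooled <- hemisphere_tests$main$p > 0.05 && hemisphere_tests$by_area$p > 0.05
  if (!pooled)
    warning("hemisphere effect significant; pooled analysis reported anyway, flagged")

  densities <- aggregateSubject(slice_densities, pool_hemispheres = TRUE)
  densities$group <- groups[match(densities$subject_id,
                                  sprintf("Z%02d", seq_len(n_subj)))]

  anova <- mixedAnova(densities, "cells_per_mm2", "subject_id",
                      "area_label", "group")
  pairwise <- pairwiseBonferroni(densities, "cells_per_mm2", "subject_id",
                                 "area_label", "group")

  sc_dens <- densities[densities$group == "STOP-CHANGE", ]
  correlations <- lapply(c("NIML", "MM", "NMm"), function(a) {
    d <- sc_dens[sc_dens$area_label == a, ]
    d <- merge(d, slope_tab, by = "subject_id")
    spearmanTest(d$slope, d$cells_per_mm2)
  })
  names(correlations) <- c("NIML", "MM", "NMm")

  res <- list(slice_densities = slice_densities, densities = densities,
              hemisphere_tests = hemisphere_tests, pooled = pooled,
              anova = anova, pairwise = pairwise,
              correlations = correlations, slopes = slope_tab, band = band,
              alpha_correlations = bonferroniAlpha(0.05, 3), seed = seed)
  if (!is.null(out_dir)) writeZenkOutputs(res, out_dir)
  res
}

writeZenkOutputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$slice_densities, file.path(out_dir, "densities.csv"),
            row.names = FALSE)
  write.csv(res$densities, file.path(out_dir, "densities_aggregated.csv"),
            row.names = FALSE)
  stats <- list(
    seed = res$seed, pooled_hemispheres = res$pooled,
    anova = res$anova$effects, pairwise = res$pairwise,
    correlations = lapply(res$correlations, function(s)
      s[c("rho", "p.value", "n", "method")]),
    alpha_correlations = res$alpha_correlations,
    threshold_band = c(lower = res$band@lower, upper = res$band@upper))
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Render a combined run report
#'
#' Assembles the behavioral and histology results into a markdown report
#' and a JSON file whose numbers equal the upstream tables. Missing stage
#' output is an error listing the absent inputs.
#'
#' @param behavior Result of [runBehaviorExperiment()], or NULL.
#' @param zenk Result of [runZenkExperiment()], or NULL.
#' @param out_dir Output directory for `report.md` and `report.json`.
#' @return Invisibly, the report list written to JSON.
#' @export
runReport <- function(behavior = NULL, zenk = NULL, out_dir) {
  if (is.null(behavior) && is.null(zenk))
    stop("missing stage outputs: need behavior and/or zenk results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# STOP-CHANGE synthetic experiment report", "")
  rep <- list()
  if (!is.null(behavior)) {
    lines <- c(lines, "## Behavior (pigeon vs human)", "",
               sprintf("Master seed: %s; Bonferroni alpha %.4f", behavior$seed,
                       behavior$alpha), "",
               "measure | group | mean | sem | n",
               "--- | --- | --- | --- | ---",
               sprintf("%s | %s | %.2f | %s | %d", behavior$groups$measure,
                       behavior$groups$group, behavior$groups$mean,
                       ifelse(is.na(behavior$groups$sem), "NA",
                              sprintf("%.3f", behavior$groups$sem)),
                       behavior$groups$n), "",
               sprintf("Interaction BF01 = %.4f", behavior$bf01$bf01), "")
    rep$behavior <- list(groups = behavior$groups,
                         anova = behavior$anova$effects,
                         t_tests = lapply(behavior$t_tests, function(t)
                           t[c("statistic", "df", "p.value")]),
                         bf01 = behavior$bf01$bf01, seed = behavior$seed)
    if (any(behavior$subjects$negative_ssrt))
      lines <- c(lines, "WARNING: negative SSRT estimates present.", "")
  }
  if (!is.null(zenk)) {
    lines <- c(lines, "## Histology (ZENK densities)", "",
               sprintf("Hemispheres pooled: %s", zenk$pooled), "",
               "area | group | mean cells/mm^2",
               "--- | --- | ---")
    agg <- aggregate(cells_per_mm2 ~ area_label + group, zenk$densities, mean)
    lines <- c(lines, sprintf("%s | %s | %.1f", agg$area_label, agg$group,
                              agg$cells_per_mm2), "",
               sprintf("Slope correlations (alpha %.4f): %s",
                       zenk$alpha_correlations,
                       paste(sprintf("%s rho=%.3f p=%.3f", names(zenk$correlations),
                                     vapply(zenk$correlations, `[[`, 1, "rho"),
                                     vapply(zenk$correlations, `[[`, 1, "p.value")),
                             collapse = "; ")), "")
    if (any(!zenk$densities$complete))
      lines <- c(lines, "WARNING: subjects with missing slices present.", "")
    rep$zenk <- list(group_area_means = agg, anova = zenk$anova$effects,
                     correlations = lapply(zenk$correlations, function(s)
                       s[c("rho", "p.value", "n")]),
                     pooled = zenk$pooled, seed = zenk$seed)
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(rep)
}
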