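#' Pipeline run configuration
#'
#' Validated container of every tunable the end-to-end synthetic run uses.
#' Validation failures abort before any computation with field-level
#' messages.
#'
#' @param seed mandatory RNG seed driving cohort generation, segmentation
#'   noise, observer marks, and eye selection.
#' @param n_control,n_albinism group sizes.
#' @param n_ascans A-scan columns per synthetic scan.
#' @param nominal_length_mm nominal scan length (mm).
#' @param axial_um_per_px axial image scale (um/px).
#' @param seg_noise_sd_px per-boundary segmentation jitter SD (px); two
#'   repeat segmentations are drawn per scan.
#' @param observer_sd_mm SD (mm) of each simulated observer's foveal mark on
#'   scans analysed by manual localization.
#' @param n_repeats repeat segmentations per scan (averaged before AUC).
#' @param step_mm,halfwidth_mm interpolation grid settings.
#' @param threshold,max_frames,strip_width_px registration settings (used
#'   when stacks are rendered).
#' @param alpha significance threshold for group tests.
#' @param ranges cohort parameter ranges, see [cohort_ranges()].
#' @return object of class `run_config`.
#' @export
run_config <- function(seed, n_control = 25, n_albinism = 30, n_ascans = 600,
                       nominal_length_mm = 6, axial_um_per_px = 3.24,
                       seg_noise_sd_px = 0.5, observer_sd_mm = 0.03,
                       n_repeats = 2, step_mm = 0.1, halfwidth_mm = 2.5,
                       threshold = 0.85, max_frames = 30, strip_width_px = 64,
                       alpha = 0.05, ranges = cohort_ranges()) {
  if (missing(seed)) abort("config$seed: a seed is mandatory.")
  checks <- list(
    seed = is.numeric(seed) && length(seed) == 1 && is.finite(seed),
    n_control = n_control >= 1, n_albinism = n_albinism >= 1,
    n_ascans = n_ascans >= 100,
    nominal_length_mm = nominal_length_mm > 0,
    axial_um_per_px = axial_um_per_px > 0,
    seg_noise_sd_px = seg_noise_sd_px >= 0,
    observer_sd_mm = observer_sd_mm >= 0,
    n_repeats = n_repeats >= 1,
    step_mm = step_mm > 0, halfwidth_mm = halfwidth_mm > 0,
    threshold = threshold > 0 && threshold <= 1,
    max_frames = max_frames >= 1,
    strip_width_px = strip_width_px >= 8,
    alpha = alpha > 0 && alpha < 1
  )
  bad <- names(checks)[!vapply(checks, isTRUE, TRUE)]
  if (length(bad)) {
    abort(paste0("Invalid config field(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(seed = seed, n_control = n_control, n_albinism = n_albinism,
                 n_ascans = n_ascans, nominal_length_mm = nominal_length_mm,
                 axial_um_per_px = axial_um_per_px,
                 seg_noise_sd_px = seg_noise_sd_px,
                 observer_sd_mm = observer_sd_mm, n_repeats = n_repeats,
                 step_mm = step_mm, halfwidth_mm = halfwidth_mm,
                 threshold = threshold, max_frames = max_frames,
                 strip_width_px = strip_width_px, alpha = alpha,
                 ranges = ranges),
            class = "run_config")
}

#' Simulate the scan set for a synthetic cohort
#'
#' Generates the cohort table, then for every participant, available eye,
#' orientation, and repeat, a noisy segmentation of the ground-truth
#' contours plus (for albinism-style manual localization) two simulated
#' observer marks. Seed-deterministic.
#'
#' @param config a [run_config()].
#' @return list: `cohort` tibble, `scans` tibble with one row per
#'   (participant, eye, orientation) and list-columns `repeats` (contour
#'   objects) and `marks_mm` (observer marks, albinism only).
#' @export
simulate_cohort_scans <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- make_cohort(config$n_control, config$n_albinism,
                        seed = config$seed, ranges = config$ranges)
  grid <- tidyr::expand_grid(
    participant = cohort$participant,
    eye = c("OD", "OS"),
    orientation = c("horizontal", "vertical")
  ) |>
    left_join(select(cohort, "participant", "group", "has_od", "has_os",
                     "al_od_mm", "al_os_mm"),
              by = "participant") |>
    filter((.data$eye == "OD" & .data$has_od) | (.data$eye == "OS" & .data$has_os)) |>
    mutate(axial_length_mm = ifelse(.data$eye == "OD", .data$al_od_mm, .data$al_os_mm))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    ph <- cohort_phenotype(cohort[cohort$participant == row$participant, ])
    sub_seed <- (config$seed + 7919 * i) %% 2147483647
    # a short eye (axial length below the coverage limit) yields a scan that
    # cannot reach +/- halfwidth; it is carried as an excluded scan, not an
    # abort, mirroring the study's exclusion accounting
    reps <- tryCatch(
      lapply(seq_len(config$n_repeats), function(r) {
        make_boundary_profiles(
          ph, orientation = row$orientation, eye = row$eye,
          n_ascans = config$n_ascans,
          nominal_length_mm = config$nominal_length_mm,
          axial_length_mm = row$axial_length_mm,
          axial_um_per_px = config$axial_um_per_px,
          seg_noise_sd_px = config$seg_noise_sd_px,
          seed = (sub_seed + r) %% 2147483647)
      }),
      error = function(e) NULL)
    true_center <- if (!is.null(reps)) {
      reps[[1]]$meta$center_col * reps[[1]]$meta$um_per_ascan / 1000
    } else {
      NA_real_
    }
    marks <- if (row$group == "albinism" && !is.null(reps)) {
      with_seed((sub_seed + 101) %% 2147483647,
                true_center + rnorm(2, 0, config$observer_sd_mm))
    } else {
      NULL
    }
    rows[[i]] <- tibble(
      participant = row$participant, group = row$group, eye = row$eye,
      orientation = row$orientation, axial_length_mm = row$axial_length_mm,
      repeats = list(reps), marks_mm = list(marks)
    )
  }
  list(cohort = cohort, scans = bind_rows(rows))
}

#' Analyse a scan set into metrics and group statistics
#'
#' For each scan: layer thickness extraction, foveal localization (DoG fit
#' of the TRT for control scans, averaged observer marks for albinism
#' scans), signed-eccentricity recentring, interpolation to the 51-sample
#' grid, repeat averaging, and per-quadrant AUC. Scans that fail (short
#' coverage, non-foveal) are excluded with a coded reason; every scan
#' appears exactly once in the inclusion log. Metrics from horizontal and
#' vertical scans of the same participant-eye are then combined, one eye
#' per participant is selected at random, and the group statistics (summed
#' AUC, N:T and S:I ratios per layer) are computed through the normality
#' gate.
#'
#' @param sim result of [simulate_cohort_scans()] (or a compatible list
#'   with `cohort` and `scans`).
#' @param config a [run_config()].
#' @return list of class `fovtopo_run`: `cohort`, `metrics` (per
#'   participant-eye-layer), `selected` (one-eye metrics used in group
#'   tests), `stats` (tibble of group comparisons), `demographics`, `log`
#'   (per-scan inclusion record).
#' @export
analyze_scans <- function(sim, config) {
  stopifnot(inherits(config, "run_config"))
  scans <- sim$scans
  cohort <- sim$cohort
  grids <- vector("list", nrow(scans))
  log_rows <- vector("list", nrow(scans))
  for (i in seq_len(nrow(scans))) {
    row <- scans[i, ]
    res <- tryCatch({
      reps <- row$repeats[[1]]
      if (is.null(reps)) rlang::abort("SHORT_COVERAGE: scan does not reach the analysis halfwidth.")
      # the fovea is located once per scan (on the first segmentation for
      # control scans, from observer marks for albinism) and the center is
      # shared by the repeat segmentations of that scan
      center <- if (row$group == "control") {
        fit_dog_center(thickness_profiles(reps[[1]]))
      } else {
        observer_center(row$marks_mm[[1]])
      }
      gridded <- lapply(reps, function(cc) {
        prof <- thickness_profiles(cc)
        ecc <- eccentricity_axis(prof, center, eye = row$eye,
                                 orientation = row$orientation)
        interpolate_grid(ecc, step_mm = config$step_mm,
                         halfwidth_mm = config$halfwidth_mm)
      })
      g <- Reduce(average_repeats, gridded)
      list(grid = g, included = TRUE, reason = "included")
    }, error = function(e) {
      msg <- conditionMessage(e)
      code <- if (grepl("SHORT_COVERAGE", msg)) "SHORT_COVERAGE"
              else if (grepl("NO_FRAMES_PASS_NCC", msg)) "NO_FRAMES_PASS_NCC"
              else "ANALYSIS_ERROR"
      list(grid = NULL, included = FALSE, reason = code)
    })
    grids[i] <- list(res$grid)
    log_rows[[i]] <- tibble(participant = row$participant, eye = row$eye,
                            orientation = row$orientation,
                            included = res$included, reason = res$reason)
  }
  scan_log <- bind_rows(log_rows)
  scans$grid <- grids
  metrics <- scans |>
    group_by(.data$participant, .data$group, .data$eye) |>
    group_modify(function(df, key) {
      gh <- df$grid[df$orientation == "horizontal"]
      gv <- df$grid[df$orientation == "vertical"]
      gh <- if (length(gh) && !is.null(gh[[1]])) gh[[1]] else NULL
      gv <- if (length(gv) && !is.null(gv[[1]])) gv[[1]] else NULL
      if (is.null(gh) && is.null(gv)) return(tibble())
      quadrant_metrics(gh, gv)
    }) |>
    ungroup()
  selected <- cohort |>
    select_random_eye(seed = config$seed + 1) |>
    select("participant", "eye") |>
    inner_join(metrics, by = c("participant", "eye"))
  stat_rows <- list()
  for (ly in c("GCL", "IPL")) {
    for (metric in c("auc_sum", "ratio_NT", "ratio_SI")) {
      vals <- selected[selected$layer == ly, ]
      a <- vals[[metric]][vals$group == "albinism"]
      ctrl <- vals[[metric]][vals$group == "control"]
      a <- a[!is.na(a)]; ctrl <- ctrl[!is.na(ctrl)]
      if (length(a) < 2 || length(ctrl) < 2) next
      cmp <- compare_groups(ctrl, a, alpha = config$alpha)
      stat_rows[[paste(ly, metric)]] <- tibble(
        layer = ly, metric = metric, test = cmp$test,
        statistic = cmp$statistic, df = cmp$df, p = cmp$p,
        gate = cmp$gate$reason,
        mean_control = mean(ctrl), sd_control = sd(ctrl),
        mean_albinism = mean(a), sd_albinism = sd(a),
        n_control = length(ctrl), n_albinism = length(a),
        significant = cmp$p < config$alpha
      )
    }
  }
  structure(list(
    cohort = cohort, metrics = metrics, selected = selected,
    stats = bind_rows(stat_rows),
    demographics = demographics_summary(cohort),
    log = scan_log
  ), class = "fovtopo_run")
}

#' Run the full synthetic pipeline
#'
#' [simulate_cohort_scans()] followed by [analyze_scans()]; end-to-end
#' deterministic under the config seed.
#'
#' @param config a [run_config()].
#' @return a `fovtopo_run`, see [analyze_scans()].
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 1, n_control = 4, n_albinism = 4,
#'                                n_ascans = 300))
#' run$stats
#' }
run_pipeline <- function(config) {
  analyze_scans(simulate_cohort_scans(config), config)
}

#' @export
print.fovtopo_run <- function(x, ...) {
  cat(sprintf("<fovtopo_run> %d participants, %d scans analysed (%d excluded)\n",
              nrow(x$cohort), sum(x$log$included), sum(!x$log$included)))
  print(x$stats)
  invisible(x)
}

#' Demographic summary and group tests for a cohort table
#'
#' Per-group mean and sample SD of age, percent female, mean and SD axial
#' length (per-eye values pooled), with the age and axial-length group
#' comparison through the normality gate and the sex distribution compared
#' by Yates-corrected chi-square.
#'
#' @param cohort tibble with `group`, `age`, `sex` and axial-length columns
#'   (`al_od_mm`/`al_os_mm`).
#' @return list: `summary` tibble (one row per group), `age_test`,
#'   `al_test` (`group_comparison` objects), `sex_test` (`chisq_2x2`).
#' @export
demographics_summary <- function(cohort) {
  if (!all(c("group", "age", "sex") %in% names(cohort))) {
    abort("`cohort` needs columns `group`, `age`, `sex`.")
  }
  groups <- unique(cohort$group)
  if (length(groups) < 1 || any(table(cohort$group) == 0)) {
    abort("Every group must be nonempty.")
  }
  # one axial length per participant (mean of available eyes), so the group
  # test weights each participant once
  al_long <- function(df) {
    m <- rowMeans(cbind(df$al_od_mm %||% rep(NA_real_, nrow(df)),
                        df$al_os_mm %||% rep(NA_real_, nrow(df))),
                  na.rm = TRUE)
    m[is.finite(m)]
  }
  summ <- cohort |>
    group_by(.data$group) |>
    summarise(n = n(), age_mean = mean(.data$age), age_sd = sd(.data$age),
              pct_female = 100 * mean(.data$sex == "F"), .groups = "drop")
  summ$al_mean <- vapply(summ$group, function(g) mean(al_long(cohort[cohort$group == g, ])), 0, USE.NAMES = FALSE)
  summ$al_sd <- vapply(summ$group, function(g) sd(al_long(cohort[cohort$group == g, ])), 0, USE.NAMES = FALSE)
  out <- list(summary = summ)
  if (length(groups) == 2) {
    g1 <- cohort[cohort$group == groups[1], ]
    g2 <- cohort[cohort$group == groups[2], ]
    out$age_test <- compare_groups(g1$age, g2$age)
    out$al_test <- compare_groups(al_long(g1), al_long(g2))
    sex_tab <- matrix(c(sum(g1$sex == "F"), sum(g1$sex == "M"),
                        sum(g2$sex == "F"), sum(g2$sex == "M")),
                      nrow = 2, byrow = TRUE)
    out$sex_test <- chi_square_2x2(sex_tab)
  }
  out
}

#' Packaged study demographics tables
#'
#' The control and albinism participant tables (participant, race, age,
#' sex, per-eye axial length, and best-corrected visual acuity for the
#' albinism group) shipped as plain-CSV fixtures so demographic summaries
#' can be recomputed offline.
#'
#' @param group `"control"`, `"albinism"`, or `"both"`.
#' @return tibble with a `group` column; `al_od_mm`/`al_os_mm` are NA where
#'   not measured.
#' @export
load_study_demographics <- function(group = c("both", "control", "albinism")) {
  group <- match.arg(group)
  read_one <- function(file, g) {
    path <- system.file("extdata", file, package = "fovtopo", mustWork = TRUE)
    df <- as_tibble(utils::read.csv(path, na.strings = c("NA", "ND")))
    df$group <- g
    df
  }
  out <- switch(group,
    control = read_one("table1_controls.csv", "control"),
    albinism = read_one("table2_albinism.csv", "albinism"),
    both = bind_rows(read_one("table1_controls.csv", "control"),
                     read_one("table2_albinism.csv", "albinism"))
  )
  rename(out, age = "age_years")
}
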