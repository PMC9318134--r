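# Orchestrate the full in-silico agreement study: synthetic fields, two
# emulated observers measuring each field twice with both methods, then
# the ICC / Bland-Altman / correlation tables.

#' Configuration of an in-silico method-agreement study
#'
#' Defaults reproduce the agreement design: 100 clean (GOOD) and 100
#' noisy-background (NOISE) pictures, each measured by 2 observers at 2
#' timepoints with both the 594-point counting grid (MC) and color-range
#' selection at fuzziness 100 (DC).
#'
#' Observer/timepoint variability is injected explicitly: each
#' observer-timepoint DC pass re-samples its reference color with Gaussian
#' per-channel jitter (`observer_color_sd`); MC passes either flip each
#' grid point's oracle classification with a small probability
#' (`mc_mode = "oracle"`, `mc_flip_rate` — human counting slips,
#' regime-independent) or jitter the color-rule tolerance
#' (`mc_mode = "color_rule"`, `mc_tolerance_sd`).
#'
#' @param n_good,n_noise numbers of GOOD / NOISE fields.
#' @param extent field size in pixels.
#' @param fraction_range true stained-fraction range, percent.
#' @param noise_intensity haze intensity of the NOISE fields, \[0, 1\].
#' @param grid a [grid_spec()] for MC.
#' @param fuzziness DC fuzziness tolerance.
#' @param stain_color true DAB reference color of the generator.
#' @param observer_color_sd SD (8-bit units/channel) of each
#'   observer-timepoint's DC reference-color jitter.
#' @param mc_mode `"oracle"` or `"color_rule"` observer surrogate for MC.
#' @param mc_flip_rate per-point misclassification probability in oracle
#'   mode.
#' @param mc_tolerance_sd SD of the color-rule tolerance jitter.
#' @param alpha significance level recorded in the report.
#' @param loa_multiplier Bland-Altman limits half-width in SD units.
#' @param seed master seed; the whole study is a deterministic function of
#'   it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_good = 100L, n_noise = 100L,
                         extent = c(512L, 512L),
                         fraction_range = c(1, 30),
                         noise_intensity = 0.5,
                         grid = grid_spec(),
                         fuzziness = 100,
                         stain_color = DEFAULT_STAIN_COLOR,
                         observer_color_sd = 4,
                         mc_mode = c("oracle", "color_rule"),
                         mc_flip_rate = 0.01,
                         mc_tolerance_sd = 8,
                         alpha = 0.05,
                         loa_multiplier = 1.96,
                         seed = 1L) {
  stopifnot(is_count(n_good), is_count(n_noise), n_good + n_noise > 0,
            inherits(grid, "grid_spec"))
  structure(
    list(n_good = as.integer(n_good), n_noise = as.integer(n_noise),
         extent = as.integer(extent), fraction_range = fraction_range,
         noise_intensity = noise_intensity, grid = grid,
         fuzziness = fuzziness, stain_color = as.integer(stain_color),
         observer_color_sd = observer_color_sd,
         mc_mode = match.arg(mc_mode), mc_flip_rate = mc_flip_rate,
         mc_tolerance_sd = mc_tolerance_sd, alpha = alpha,
         loa_multiplier = loa_multiplier, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Save / load a study configuration (YAML, lossless round-trip)
#'
#' @param config a [study_config()].
#' @param path a `.yaml` file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` the restored `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  obj <- unclass(config)
  obj$grid <- unclass(obj$grid)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$grid
  obj$grid <- grid_spec(g$n_rows, g$n_cols, g$placement, g$seed)
  obj$extent <- as.integer(obj$extent)
  do.call(study_config, obj[setdiff(names(obj), character(0))])
}

#' Run the in-silico agreement study
#'
#' Generates the synthetic picture set, has two emulated observers measure
#' every field twice (T1, T2) with both MC and DC, and computes:
#' intraobserver ICC (T1 vs T2) per observer and method; interobserver ICC
#' (observer 1 vs 2 at T1) per method and regime; Bland-Altman DC - MC
#' (observer 1, T1) per regime; and Pearson correlations (plain and
#' difference-vs-mean) per regime. Per-image wall-clock time is recorded
#' as informational metadata only.
#'
#' @param config a [study_config()].
#' @param output_dir optional directory; when given, writes
#'   `measurements.csv`, `icc_intra.csv`, `icc_inter.csv`,
#'   `bland_altman.csv`, and `summary.json` (plus Bland-Altman plots when
#'   `plots = TRUE`).
#' @param plots also write `ba_good.png` / `ba_noise.png`.
#' @return An object of class `study_report`: list with `measurements`,
#'   `icc_intra`, `icc_inter`, `bland_altman`, `correlations`, `timing`,
#'   and the `config`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL,
                      plots = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$seed, 16L)
  fields <- generate_study_fixtures(
    config$n_good, config$n_noise, seed = seeds[1],
    extent = config$extent, fraction_range = config$fraction_range,
    noise_intensity = config$noise_intensity
  )
  grid <- build_grid(config$grid, config$extent)
  n_points <- nrow(grid)

  # one reference-color / tolerance / flip seed per observer x timepoint
  obs_tp <- expand.grid(observer = 1:2, timepoint = 1:2)
  pass_seed <- derive_seeds(seeds[2], nrow(obs_tp))
  passes <- lapply(seq_len(nrow(obs_tp)), function(i) {
    with_seed(pass_seed[i], {
      list(
        observer = obs_tp$observer[i],
        timepoint = obs_tp$timepoint[i],
        dc_ref = as.integer(clip(round(
          config$stain_color + rnorm(3, 0, config$observer_color_sd)
        ), 0, 255)),
        mc_tolerance = 100 + rnorm(1, 0, config$mc_tolerance_sd),
        flip_seed = sample.int(.Machine$integer.max - 1L, 1)
      )
    })
  })

  rows <- vector("list", length(fields) * nrow(obs_tp) * 2L)
  timing <- c(MC = 0, DC = 0)
  ri <- 0L
  for (f in fields) {
    oracle_hits <- classify_points(f, grid, hit_classifier("oracle_mask"))
    for (p in passes) {
      t0 <- proc.time()[["elapsed"]]
      if (config$mc_mode == "oracle") {
        flips <- with_seed(
          pass_seed_for(p$flip_seed, f$field_id),
          rbinom(n_points, 1L, config$mc_flip_rate) == 1L
        )
        hits <- xor(oracle_hits, flips)
        mc_val <- 100 * sum(hits) / n_points
      } else {
        cls <- hit_classifier("color_rule", reference_color = p$dc_ref,
                              tolerance = p$mc_tolerance)
        mc_val <- as.numeric(mc_area_fraction(f, grid, cls))
      }
      t1 <- proc.time()[["elapsed"]]
      dc_val <- as.numeric(dc_area_fraction(
        f, color_range_spec(p$dc_ref, fuzziness = config$fuzziness)
      ))
      t2 <- proc.time()[["elapsed"]]
      timing <- timing + c(MC = t1 - t0, DC = t2 - t1)
      for (meth in c("MC", "DC")) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          field_id = f$field_id, regime = f$regime,
          true_fraction = f$true_fraction, method = meth,
          observer = p$observer, timepoint = p$timepoint,
          value = if (meth == "MC") mc_val else dc_val
        )
      }
    }
  }
  measurements <- do.call(rbind, rows)

  get_vals <- function(meth, obs, tp, regime = NULL) {
    sel <- measurements$method == meth & measurements$observer == obs &
      measurements$timepoint == tp
    if (!is.null(regime)) sel <- sel & measurements$regime == regime
    m <- measurements[sel, ]
    m[order(m$field_id), ]
  }
  icc_row <- function(icc, ...) {
    data.frame(..., icc = icc$icc, variance = icc$variance_between,
               error = icc$variance_error, p_value = icc$p_value,
               label = icc$label)
  }

  # intraobserver: T1 vs T2, all fields pooled
  icc_intra <- do.call(rbind, lapply(
    split(expand.grid(observer = 1:2, method = c("MC", "DC"),
                      stringsAsFactors = FALSE), seq_len(4)),
    function(g) {
      a <- get_vals(g$method, g$observer, 1)
      b <- get_vals(g$method, g$observer, 2)
      icc_row(icc_oneway(data.frame(value_a = a$value, value_b = b$value)),
              observer = g$observer, method = g$method,
              comparison = "T1_vs_T2")
    }
  ))

  # interobserver: observer 1 vs 2 at T1, per regime
  icc_inter <- do.call(rbind, lapply(
    split(expand.grid(method = c("MC", "DC"), regime = c("GOOD", "NOISE"),
                      stringsAsFactors = FALSE), seq_len(4)),
    function(g) {
      if (sum(measurements$regime == g$regime) == 0) return(NULL)
      a <- get_vals(g$method, 1, 1, g$regime)
      b <- get_vals(g$method, 2, 1, g$regime)
      icc_row(icc_oneway(data.frame(value_a = a$value, value_b = b$value)),
              method = g$method, regime = g$regime,
              comparison = "obs1_vs_obs2_T1")
    }
  ))

  # Bland-Altman DC - MC and correlations, observer 1 at T1, per regime
  ba_list <- list(); ba_rows <- list(); cor_rows <- list()
  for (regime in unique(measurements$regime)) {
    mc <- get_vals("MC", 1, 1, regime)
    dc <- get_vals("DC", 1, 1, regime)
    ps <- data.frame(value_a = mc$value, value_b = dc$value)
    ba <- bland_altman(ps, multiplier = config$loa_multiplier)
    ba$sign_convention <- "DC - MC"
    ba_list[[regime]] <- ba
    ba_rows[[regime]] <- data.frame(
      regime = regime, bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      coverage = ba$coverage, n = ba$n, sign_convention = ba$sign_convention
    )
    cor_rows[[regime]] <- data.frame(
      regime = regime,
      pearson_plain = pearson_r(mc$value, dc$value, "plain"),
      pearson_diff_vs_mean = tryCatch(
        pearson_r(mc$value, dc$value, "diff_vs_mean"),
        error = function(e) NA_real_
      )
    )
  }
  bland_altman_tab <- do.call(rbind, ba_rows)
  correlations <- do.call(rbind, cor_rows)
  n_passes <- length(fields) * nrow(obs_tp)
  report <- structure(
    list(measurements = measurements, icc_intra = icc_intra,
         icc_inter = icc_inter, bland_altman = bland_altman_tab,
         correlations = correlations,
         timing = list(mean_seconds_per_image = timing / n_passes),
         config = config),
    class = "study_report"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(measurements, file.path(output_dir, "measurements.csv"),
              row.names = FALSE)
    write.csv(icc_intra, file.path(output_dir, "icc_intra.csv"),
              row.names = FALSE)
    write.csv(icc_inter, file.path(output_dir, "icc_inter.csv"),
              row.names = FALSE)
    write.csv(bland_altman_tab, file.path(output_dir, "bland_altman.csv"),
              row.names = FALSE)
    summary_obj <- list(
      design = list(n_good = config$n_good, n_noise = config$n_noise,
                    n_observers = 2L, n_timepoints = 2L,
                    n_measurements = nrow(measurements)),
      icc_intra = icc_intra, icc_inter = icc_inter,
      bland_altman = bland_altman_tab, correlations = correlations,
      timing = report$timing, seed = config$seed
    )
    jsonlite::write_json(summary_obj, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (plots) {
      for (regime in names(ba_list)) {
        fn <- file.path(output_dir,
                        paste0("ba_", tolower(regime), ".png"))
        grDevices::png(fn, width = 900, height = 700, res = 120)
        print(plot_bland_altman(ba_list[[regime]],
                                title = paste("DC vs MC,", regime)))
        grDevices::dev.off()
      }
    }
  }
  report
}

# Stable per-field sub-seed: combine a pass seed with a field id hash.
pass_seed_for <- function(seed, field_id) {
  h <- sum(utf8ToInt(field_id) * seq_along(utf8ToInt(field_id)))
  (as.double(seed) + 7919 * h) %% (.Machine$integer.max - 1)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("In-silico agreement study: %d GOOD + %d NOISE fields, %d measurements\n",
              x$config$n_good, x$config$n_noise, nrow(x$measurements)))
  cat("\nInterobserver ICC:\n")
  print(x$icc_inter, row.names = FALSE)
  cat("\nBland-Altman (DC - MC):\n")
  print(x$bland_altman, row.names = FALSE)
  invisible(x)
}
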