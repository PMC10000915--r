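#' Load and validate a run configuration
#'
#' The configuration is a YAML file with a `seed`, a `paradigm` block and
#' optional per-modality generator blocks (`bold`, `ephys`, `resting`,
#' `po2`) plus an `analysis` block of pipeline parameters. Unknown top-level
#' keys are rejected so typos fail loudly instead of silently using
#' defaults.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("seed", "paradigm", "bold", "ephys", "resting", "po2",
             "analysis", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a seed")
  p <- cfg$paradigm
  cfg$paradigm <- do.call(stim_paradigm, if (is.null(p)) list() else p)
  defaults <- list(nu = 0.05, proto_quantile = 0.5, motion_limit = 1,
                   threshold_frac = 0.30, bin_width = 1, sd_mult = 2)
  cfg$analysis <- utils::modifyList(defaults,
                                    if (is.null(cfg$analysis)) list()
                                    else cfg$analysis)
  structure(cfg, class = "run_config")
}

# Stable hash of a config for provenance: digest of its canonical YAML text.
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(lapply(unclass(cfg), function(x)
    if (inherits(x, "stim_paradigm")) unclass(x) else x))
  # small polynomial rolling hash; enough to fingerprint a run
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_bold_block <- function() {
  list(grid = c(40, 40, 1), active_x = c(18, 23), active_y = c(18, 23),
       active_z = 1, amplitude_pct = 1.88, noise_sd_pct = 0.3,
       baseline = 1000)
}

default_po2_block <- function() {
  list(baseline_mmHg = 25.12, amplitude_pct = 4.71, noise_sd_mmHg = 0.5)
}

default_resting_block <- function() {
  list(n_units = 47, mean_rate = 3.21, sd_rate = 0.98, duration_s = 300)
}

default_ephys_block <- function() {
  list(duration_s = 20, noise_sd = 10e-6,
       units = list(list(duration_ms = 0.33, amplitude = 120e-6, rate = 6,
                         stim_mult = 1, drug_mult = 1),
                    list(duration_ms = 0.9, amplitude = 90e-6, rate = 3,
                         stim_mult = 1, drug_mult = 1)))
}

# overwrite defaults key by key; unlike modifyList this replaces nested
# blocks (e.g. the ephys unit list) wholesale instead of merging them
override <- function(defaults, user) {
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

run_log <- function(stage, ...) {
  message(sprintf("[negbold:%s] %s", stage, paste0(...)))
}

#' Run one pipeline stage from a configuration
#'
#' Deterministic, file-based entry point tying the stages together. Every
#' stage writes its artifacts under `out_dir` and logs its parameters to
#' stderr; `report` aggregates all stage outputs present in `out_dir` into
#' one JSON summary embedding the config fingerprint.
#'
#' Subcommands: `simulate` (generate and write all modality datasets),
#' `bold` (trial averaging, SVM mapping, response metrics), `ephys`
#' (artifact removal, spike detection, unit sorting, classification),
#' `resting` (change distributions and window dynamics), `evoked`
#' (peri-event histograms and magnitude comparison), `po2` (baseline and
#' response summary), `report`.
#'
#' @param config Path to a YAML config or a config list
#'   (see [load_run_config()]).
#' @param subcommand One of `simulate`, `ephys`, `resting`, `evoked`,
#'   `bold`, `po2`, `report`.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list of the stage's main results.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "ephys", "resting",
                                        "evoked", "bold", "po2", "report"),
                         out_dir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- load_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$paradigm
  an <- cfg$analysis
  seed <- as.integer(cfg$seed)
  res <- switch(subcommand,
    simulate = {
      bb <- override(default_bold_block(), cfg$bold %||% list())
      mask <- rect_mask(bb$grid, bb$active_x[1]:bb$active_x[2],
                        bb$active_y[1]:bb$active_y[2], bb$active_z)
      bt <- gen_bold_trials(p, bold_truth(mask, bb$amplitude_pct,
                                          bb$noise_sd_pct,
                                          baseline = bb$baseline,
                                          seed = derive_seed(seed, 1)),
                            grid = bb$grid)
      run_log("simulate", "BOLD: amplitude ", bb$amplitude_pct,
              "%, noise ", bb$noise_sd_pct, "%")
      write_bold_nifti(bt, file.path(out_dir, "bold"))
      ob <- override(default_po2_block(), cfg$po2 %||% list())
      pt <- gen_po2_trace(p, po2_truth(ob$baseline_mmHg, ob$amplitude_pct,
                                       ob$noise_sd_mmHg,
                                       seed = derive_seed(seed, 2)))
      write_po2_tsv(pt, file.path(out_dir, "po2.tsv"))
      eb <- override(default_ephys_block(), cfg$ephys %||% list())
      et <- ephys_truth(do.call(rbind, lapply(eb$units, as.data.frame)),
                        noise_sd = eb$noise_sd, artifact_period_s = p$tr_s,
                        seed = derive_seed(seed, 3))
      ons <- stim_onsets_s(p)
      ons <- ons[ons + p$n_stim * p$tr_s <= eb$duration_s]
      se <- if (length(ons) > 0)
        data.frame(start_s = ons, end_s = ons + p$n_stim * p$tr_s) else NULL
      rec <- gen_raw_ephys(et, eb$duration_s, stim_epochs = se)
      saveRDS_free <- file.path(out_dir, "ephys_trace.tsv")
      utils::write.table(
        data.frame(time_s = (seq_along(rec$trace) - 1) / rec$fs_hz,
                   volts = rec$trace),
        saveRDS_free, sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(rec$true_spikes,
                         file.path(out_dir, "ephys_true_spikes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      run_log("simulate", "wrote BOLD, PO2 and ephys datasets to ", out_dir)
      list(bold = bt, po2 = pt, ephys = rec)
    },
    bold = {
      bt <- read_bold_nifti(file.path(out_dir, "bold"))
      run_log("bold", "nu=", an$nu, " proto_quantile=", an$proto_quantile,
              " motion_limit=", an$motion_limit)
      out <- bold_pipeline(bt, motion_limit = an$motion_limit, nu = an$nu,
                           proto_quantile = an$proto_quantile, seed = seed)
      write_map_nifti(out$map, file.path(out_dir, "activation"))
      metrics <- list(n_active = out$map$n_active,
                      area_mm2 = out$map$area_mm2,
                      magnitude_pct = out$metrics$magnitude_pct,
                      duration_s = out$metrics$duration_s,
                      polarity = out$metrics$polarity,
                      n_trials_used = out$averaged$n_used)
      jsonlite::write_json(metrics, file.path(out_dir, "bold_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    ephys = {
      tr <- utils::read.table(file.path(out_dir, "ephys_trace.tsv"),
                              header = TRUE, sep = "\t")
      fs <- 1 / stats::median(diff(tr$time_s))
      eb <- override(default_ephys_block(), cfg$ephys %||% list())
      thr <- (eb$noise_sd %||% 10e-6) * 10
      mask <- detect_artifact_blocks(tr$volts, fs, amp_threshold = thr,
                                     erosion_len = 32, dilation_len = 64)
      clean <- excise_blocks(tr$volts, mask)
      ev <- detect_spikes(clean, k = 3)
      run_log("ephys", nrow(mask$intervals), " artifact blocks, ",
              length(ev$time_s), " candidate events")
      sorted <- assign_units(ev, seed = seed)
      dur <- max(tr$time_s)
      sorted$features$rate <- sorted$features$n_events / dur
      sorted$features$class <- mapply(classify_unit,
                                      sorted$features$duration_ms,
                                      sorted$features$rate)
      write_spikes_tsv(sorted, file.path(out_dir, "spikes.tsv"),
                       file.path(out_dir, "unit_features.tsv"))
      sorted
    },
    resting = {
      rb <- override(default_resting_block(), cfg$resting %||% list())
      trains <- read_spikes_tsv(file.path(out_dir, "spikes.tsv"))
      stop_if_empty(trains, "spikes.tsv has no units")
      dur <- max(unlist(trains))
      half <- dur / 2
      before <- vapply(trains, rate_in_window, numeric(1),
                       window = c(0, half))
      after <- vapply(trains, rate_in_window, numeric(1),
                      window = c(half, 2 * half))
      dist <- change_distribution(before, after, an$threshold_frac)
      run_log("resting", "threshold ", an$threshold_frac, ": ",
              dist$n_increase, " inc / ", dist$n_decrease, " dec / ",
              dist$n_no_change, " nc")
      out <- data.frame(unit_id = names(trains), before = before,
                        after = after, bin = dist$bins)
      utils::write.table(out, file.path(out_dir, "resting_changes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      dist
    },
    evoked = {
      trains <- read_spikes_tsv(file.path(out_dir, "spikes.tsv"))
      stop_if_empty(trains, "spikes.tsv has no units")
      onsets <- stim_onsets_s(p)
      onsets <- onsets[onsets < max(unlist(trains))]
      if (length(onsets) == 0) stop("recording does not cover any stimulus")
      pehs <- lapply(trains, build_peh, onsets = onsets,
                     bin_width = an$bin_width, normalize = TRUE)
      summaries <- mapply(function(ph, id)
        classify_response(ph, stim_duration_s = p$n_stim * p$tr_s,
                          sd_mult = an$sd_mult, unit_id = id),
        pehs, seq_along(pehs), SIMPLIFY = FALSE)
      pol <- vapply(summaries, function(s) s$polarity, character(1))
      run_log("evoked", sum(pol == "excitatory"), " excitatory of ",
              length(pol), " units")
      df <- do.call(rbind, lapply(summaries, function(s)
        data.frame(unit_id = s$unit_id, polarity = s$polarity,
                   magnitude_pct = s$magnitude_pct_of_baseline)))
      utils::write.table(df, file.path(out_dir, "evoked_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      summaries
    },
    po2 = {
      df <- read_po2_tsv(file.path(out_dir, "po2.tsv"))
      if (!"trial" %in% names(df)) df$trial <- 1
      m <- do.call(cbind, split(df$po2_mmHg, df$trial))
      fs <- 1 / stats::median(diff(df$time_s[df$trial == df$trial[1]]))
      base <- baseline_mmHg(rowMeans(m),
                            window = c(0, p$n_baseline * p$tr_s), fs_hz = fs)
      ds <- resample_to_bold(m, fs_hz = round(fs), paradigm = p)
      summ <- classify_and_average(ds$po2, paradigm = p,
                                   fs_hz = 1 / p$tr_s)
      run_log("po2", "baseline ", round(base, 2), " mmHg; above-only ",
              round(summ$mean_above_only, 2), "%, all ",
              round(summ$mean_all_trials, 2), "%")
      utils::write.table(summ$per_trial,
                         file.path(out_dir, "po2_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      c(summ, baseline_mmHg = base)
    },
    report = {
      rep <- list(config_hash = config_hash(cfg), seed = seed)
      bm <- file.path(out_dir, "bold_metrics.json")
      if (file.exists(bm)) rep$bold <- jsonlite::read_json(bm)
      rc <- file.path(out_dir, "resting_changes.tsv")
      if (file.exists(rc)) {
        df <- utils::read.table(rc, header = TRUE, sep = "\t")
        rep$resting <- as.list(table(df$bin))
      }
      ev <- file.path(out_dir, "evoked_summary.tsv")
      if (file.exists(ev)) {
        df <- utils::read.table(ev, header = TRUE, sep = "\t")
        rep$evoked <- list(n_units = nrow(df),
                           n_excitatory = sum(df$polarity == "excitatory"))
      }
      ps <- file.path(out_dir, "po2_summary.tsv")
      if (file.exists(ps)) {
        df <- utils::read.table(ps, header = TRUE, sep = "\t")
        rep$po2 <- list(n_above = sum(df$class == "above_baseline"),
                        n_below = sum(df$class == "below_baseline"),
                        mean_all_trials = mean(df$response_pct))
      }
      jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      run_log("report", "wrote report.json (config ", rep$config_hash, ")")
      rep
    })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_empty <- function(x, msg) if (length(x) == 0) stop(msg)
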