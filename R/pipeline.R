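# Declarative pipeline: simulate -> idealize -> kinetics -> features ->
# classify, driven by a plain-text (YAML) config with unit-suffixed keys.

#' Read a run configuration
#'
#' @param path YAML file.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file %s not found", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_scheme <- function(sc) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  two_state_scheme(k_on = num(sc$k_on_per_molar_s), k_off = num(sc$k_off_per_s),
                   i_p = num(sc$i_p_pA) %||% 160,
                   delta_i = num(sc$delta_i_pA) %||% -60)
}

config_noise <- function(nz) {
  if (is.null(nz)) return(noise_model(0))
  noise_model(nz$baseline_sd_pA %||% 0, nz$state_noise %||% list())
}

config_acq <- function(aq, duration = NULL) {
  aq <- aq %||% list()
  acquisition(sampling_rate = aq$sampling_rate_hz %||% 25000,
              analog_corner = aq$analog_corner_hz %||% 1000,
              filter_order = aq$filter_order %||% 4,
              filter_type = aq$filter_type %||% "bessel",
              duration = duration)
}

# Assign ground-truth mixture labels to detected events by midpoint overlap.
match_event_labels <- function(events, gt_labels) {
  mid <- (events$start_s + events$end_s) / 2
  lab <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(events))) {
    hit <- which(gt_labels$t_start <= mid[i] & gt_labels$t_end >= mid[i])
    if (length(hit)) lab[i] <- gt_labels$class[hit[1]]
  }
  lab
}

#' Run a declarative analysis pipeline
#'
#' Executes the stages present in the config, in order: `simulate`
#' (titration series and/or labelled mixture), `idealize`, `kinetics`,
#' `features` (frequency split), `classify`. Stage dependencies are checked
#' up front; every artifact embeds the hash of the config that produced it,
#' and a structured log records seeds and parameters. Identical config and
#' seed reproduce identical artifacts.
#'
#' @param config A `run_config` (or path to a YAML file, or plain list).
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisible list of in-memory results (traces, events, kinetics
#'   fit, features, classifier evaluation, artifact paths).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- unclass(config)
  out_dir <- output_dir %||% cfg$output_dir %||% stop_config("output_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  # hash covers the scientific configuration, not the output location
  chash <- hash_object(cfg[setdiff(names(cfg), "output_dir")])
  stages <- names(cfg)[names(cfg) %in%
                         c("simulate", "idealize", "kinetics", "features", "classify")]

  need <- function(stage, dep) {
    if (!dep %in% stages)
      stop_config("stage '%s' requires stage '%s' in the config", stage, dep)
  }
  if ("idealize" %in% stages) need("idealize", "simulate")
  if ("kinetics" %in% stages) need("kinetics", "idealize")
  if ("features" %in% stages) need("features", "idealize")
  if ("classify" %in% stages) need("classify", "features")

  log_file <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_file, append = TRUE)
  cat(sprintf("# pipeline log\nconfig_hash: %s\nmaster_seed: %d\n",
              chash, as.integer(seed)), file = log_file)

  res <- list(config_hash = chash, artifacts = character(0))
  titr_traces <- NULL; mix_trace <- NULL

  if ("simulate" %in% stages) {
    sim <- cfg$simulate
    if (!is.null(sim$titration)) {
      ti <- sim$titration
      sch <- config_scheme(ti$scheme)
      conc <- as.numeric(ti$concentrations_molar)
      titr_traces <- simulate_concentration_series(
        sch, conc, duration = ti$duration_s,
        noise = config_noise(ti$noise), acq = config_acq(ti$acquisition),
        seed = derive_seed(seed, 1L))
      for (i in seq_along(titr_traces)) {
        stem <- file.path(out_dir, sprintf("trace_titration_%02d", i))
        write_trace(titr_traces[[i]], stem, config_hash = chash)
        res$artifacts <- c(res$artifacts, paste0(stem, c(".json", ".f32")))
      }
      logf("simulate/titration: %d traces, conc = %s mol/L, duration = %g s",
           length(conc), paste(conc, collapse = ", "), ti$duration_s)
      res$titration <- list(traces = titr_traces, scheme = sch, conc = conc)
    }
    if (!is.null(sim$mixture)) {
      mx <- sim$mixture
      classes <- lapply(mx$classes, function(cl)
        list(scheme = config_scheme(cl$scheme), noise = config_noise(cl$noise)))
      mix_trace <- simulate_mixture(
        classes, proportions = as.numeric(mx$proportions),
        concentration = mx$concentration_molar, duration = mx$duration_s,
        baseline_sd = mx$baseline_sd_pA %||% 0,
        acq = config_acq(mx$acquisition), seed = derive_seed(seed, 2L))
      stem <- file.path(out_dir, "trace_mixture")
      write_trace(mix_trace, stem, config_hash = chash)
      res$artifacts <- c(res$artifacts, paste0(stem, c(".json", ".f32")))
      logf("simulate/mixture: %d classes, duration = %g s",
           length(classes), mx$duration_s)
      res$mixture <- list(trace = mix_trace)
    }
    if (is.null(sim$titration) && is.null(sim$mixture))
      stop_config("simulate stage needs a 'titration' and/or 'mixture' block")
  }

  if ("idealize" %in% stages) {
    idz <- cfg$idealize
    bl <- if (!is.null(idz$baseline))
      list(mean_Ip = idz$baseline$mean_Ip_pA, sd_Ip = idz$baseline$sd_Ip_pA)
    else NULL
    ideal_one <- function(tr, tag, labels = NULL) {
      b <- bl %||% estimate_baseline(tr)
      ev <- detect_events(tr, b, nominal_delta_i = idz$nominal_delta_i_pA,
                          min_duration = idz$min_duration_s %||% NULL)
      ev <- annotate_events(tr, ev)
      if (!is.null(labels)) ev$label <- match_event_labels(ev, labels)
      f <- file.path(out_dir, sprintf("events_%s.tsv", tag))
      write_events(ev, f, config_hash = chash)
      res$artifacts <<- c(res$artifacts, f)
      logf("idealize/%s: %d events (baseline %.3f pA, sd %.3f)", tag,
           nrow(ev), b$mean_Ip, b$sd_Ip)
      ev
    }
    if (!is.null(titr_traces))
      res$titration$events <- lapply(seq_along(titr_traces), function(i)
        ideal_one(titr_traces[[i]], sprintf("titration_%02d", i)))
    if (!is.null(mix_trace))
      res$mixture$events <- ideal_one(mix_trace, "mixture",
                                      labels = mix_trace$meta$event_labels)
  }

  if ("kinetics" %in% stages) {
    if (is.null(res$titration))
      stop_config("kinetics stage requires a titration block in simulate")
    kin <- cfg$kinetics %||% list()
    fit <- fit_binding_kinetics(res$titration$events,
                                concentration = res$titration$conc,
                                t_min = kin$t_min_s %||% 0,
                                method = kin$method %||% "mle")
    res$kinetics <- fit
    tsv <- file.path(out_dir, "kinetics_by_concentration.tsv")
    write.table(cbind(config_hash = chash, fit$by_concentration), tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
    rep_file <- file.path(out_dir, "kinetics_report.txt")
    con <- file(rep_file, "w")
    sink(con); cat("# config_hash:", chash, "\n"); print(summary(fit)); sink()
    close(con)
    res$artifacts <- c(res$artifacts, tsv, rep_file)
    logf("kinetics: k_on = %.4g, k_off = %.4g, K_b = %.4g",
         fit$rates$k_on, fit$rates$k_off, fit$rates$K_b)
  }

  if ("features" %in% stages) {
    if (is.null(res$mixture))
      stop_config("features stage requires a mixture block in simulate")
    fcfg <- cfg$features %||% list()
    split <- frequency_split(res$mixture$trace,
                             cutoff = fcfg$cutoff_hz %||% 100,
                             order = fcfg$order %||% 4)
    feats <- extract_features(split, res$mixture$events,
                              guard_samples = fcfg$guard_samples %||% 0L)
    feats$label <- res$mixture$events$label
    f <- file.path(out_dir, "features.tsv")
    con <- file(f, "w")
    writeLines(sprintf("# config_hash: %s", chash), con)
    write.table(feats, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    res$features <- feats
    res$artifacts <- c(res$artifacts, f)
    logf("features: %d events, cutoff = %g Hz", nrow(feats),
         fcfg$cutoff_hz %||% 100)
  }

  if ("classify" %in% stages) {
    ccfg <- cfg$classify %||% list()
    feats <- res$features[!is.na(res$features$label), , drop = FALSE]
    ev <- evaluate_classifier(feats, feats$label,
                              train_frac = ccfg$train_frac %||% 0.7,
                              cost = ccfg$cost %||% 1,
                              seed = derive_seed(seed, 3L))
    res$classifier <- ev
    mf <- file.path(out_dir, "classifier_model.rds")
    saveRDS(list(config_hash = chash, model = ev$model), mf)
    cm <- file.path(out_dir, "confusion_matrix.tsv")
    con <- file(cm, "w")
    writeLines(sprintf("# config_hash: %s", chash), con)
    write.table(as.data.frame.matrix(ev$confusion$table), con, sep = "\t",
                quote = FALSE)
    close(con)
    grid <- decision_boundary_grid(
      ev$model,
      lp_range = range(feats$lp_sd), hp_range = range(feats$hp_sd),
      resolution = ccfg$grid_resolution %||% 50L)
    gf <- file.path(out_dir, "decision_grid.tsv")
    gdf <- data.frame(lp_sd = rep(grid$lp, times = length(grid$hp)),
                      hp_sd = rep(grid$hp, each = length(grid$lp)),
                      label = as.character(grid$labels))
    con <- file(gf, "w")
    writeLines(sprintf("# config_hash: %s", chash), con)
    write.table(gdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    res$artifacts <- c(res$artifacts, mf, cm, gf)
    logf("classify: held-out overall accuracy %.3f",
         ev$confusion$overall_accuracy)
  }

  invisible(res)
}
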