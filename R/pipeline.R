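## cli_pipeline: YAML run configuration, end-to-end orchestration of the
## analysis stages, and the thin command-line dispatcher used by
## inst/cli/hjdimer.R.  All numeric output is written with fixed formats
## so identical config + seed gives byte-identical files.

.analysis_defaults <- list(
  stride_ps = 100, contact_stride_ps = 500, burn_in_ps = 1e5,
  cutoff_nm = 1.2, kappa_boundary = 1.0, dimer_r_max_nm = 1.5,
  window = c(11, 16))

.bin_defaults <- list(r_max_nm = 5, r_width_nm = 0.05, kappa_width = 0.05,
                      j_max_mev = 200, j_width_mev = 2.5)

user_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("hj_user_error", "error")))
}

#' Read and validate a run configuration
#'
#' The configuration is one YAML document describing an entire run:
#' `topology` (PDB path), `trajectories` (list of `{path, format, dt}`),
#' `dyes` (list of dye definitions: `label`, `chain`, `resno`, optional
#' `resname`, `end_r`, `end_s`, `mu_debye`), optional `coupling`
#' (`refractive_index`), `analysis` (strides, burn-in, cutoff,
#' thresholds, centre window), `bins`, optional `synth` and `junction`
#' sections.  Missing analysis/bin keys get the standard defaults
#' (orientation stride 100 ps, contact stride 500 ps, burn-in 100 ns,
#' cutoff 1.2 nm).
#'
#' @param path YAML file.
#' @return An object of class `run_config`; `$hash` is the MD5 of the
#'   config file, embedded in every output header.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) user_error("configuration error: no such config: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) user_error("configuration error: bad YAML in ",
                                                 path, ": ", conditionMessage(e)))
  cfg <- validate_run_config(raw)
  cfg$hash <- unname(tools::md5sum(path))
  cfg$dir <- dirname(normalizePath(path))
  cfg
}

#' Validate a run-configuration list
#'
#' @param raw named list with the structure documented in
#'   [read_run_config()].
#' @return An object of class `run_config`.
#' @export
validate_run_config <- function(raw) {
  if (!is.list(raw)) user_error("configuration error: config must be a mapping")
  cfg <- raw
  cfg$analysis <- modifyList(.analysis_defaults, raw$analysis %||% list())
  cfg$bins <- modifyList(.bin_defaults, raw$bins %||% list())
  a <- cfg$analysis
  if (a$stride_ps <= 0 || a$contact_stride_ps <= 0 || a$burn_in_ps < 0)
    user_error("configuration error: strides must be positive, burn-in >= 0")
  if (!is.null(raw$dyes)) {
    cfg$dyes <- lapply(raw$dyes, function(d) {
      tryCatch(
        dye_definition(label = d$label, chain = d$chain, resno = d$resno,
                       resname = d$resname, end_r = unlist(d$end_r),
                       end_s = unlist(d$end_s),
                       mu_debye = d$mu_debye %||% 0),
        error = function(e) user_error(conditionMessage(e)))
    })
  }
  if (!is.null(raw$trajectories)) {
    for (tr in raw$trajectories)
      if (is.null(tr$path))
        user_error("configuration error: trajectory entry without a path")
  }
  cfg$coupling_cfg <- coupling_config(
    (raw$coupling %||% list())$refractive_index %||% 1.33)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  if (!is.null(config$hash)) return(config$hash)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)[order(names(unclass(config)))]), tmp)
  unname(tools::md5sum(tmp))
}

resolve_path <- function(path, config) {
  if (file.exists(path) || is.null(config$dir)) return(path)
  file.path(config$dir, path)
}

load_trials <- function(config) {
  if (is.null(config$topology) || is.null(config$trajectories))
    user_error("configuration error: topology and trajectories are required")
  topo <- read_structure(resolve_path(config$topology, config))$topology
  lapply(config$trajectories, function(tr)
    read_trajectory(topo, resolve_path(tr$path, config),
                    format = tr$format %||% "pdb", dt = tr$dt))
}

output_header <- function(config, extra = NULL) {
  a <- config$analysis
  c(sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# stride_ps: %g", a$stride_ps),
    sprintf("# burn_in_ps: %g", a$burn_in_ps),
    sprintf("# cutoff_nm: %g", a$cutoff_nm),
    sprintf("# kappa_boundary: %g", a$kappa_boundary),
    sprintf("# dimer_r_max_nm: %g", a$dimer_r_max_nm),
    if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra))
}

write_observations <- function(obs, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  cols <- names(obs)
  writeLines(c(header, paste(cols, collapse = "\t")), con)
  fmt <- paste(rep("%.8g", length(cols)), collapse = "\t")
  writeLines(do.call(sprintf, c(list(fmt), unname(as.list(obs)))), con)
  invisible(path)
}

#' Run the orientation/coupling analysis stage
#'
#' For each trial trajectory: per-frame dimer observations at the
#' orientation stride after burn-in (time, R, kappa, |kappa|, and J,
#' |J| when the dyes carry dipole magnitudes), written as
#' `<prefix>_trial<i>_observations.tsv`.  A pooled multi-trial summary
#' with classification tallies is written as `<prefix>_summary.json`.
#'
#' @param config a `run_config`.
#' @param out_prefix output path prefix.
#' @return The [summarize_trials()] object, invisibly.
#' @export
pipeline_analyze <- function(config, out_prefix) {
  trials <- load_trials(config)
  if (length(config$dyes %||% list()) != 2L)
    user_error("configuration error: analyze needs exactly two dyes")
  a <- config$analysis
  hdr <- output_header(config)
  obs <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    obs[[i]] <- observe_dimer(trials[[i]], config$dyes[[1]], config$dyes[[2]],
                              stride = a$stride_ps, burn_in = a$burn_in_ps,
                              coupling = config$coupling_cfg)
    write_observations(obs[[i]],
                       sprintf("%s_trial%d_observations.tsv", out_prefix, i),
                       hdr)
  }
  summ <- summarize_trials(obs)
  pooled <- do.call(rbind, obs)
  cls <- classify_dimer(pooled$abs_kappa, pooled$R_nm,
                        kappa_boundary = a$kappa_boundary,
                        dimer_r_max = a$dimer_r_max_nm)
  tal <- as.list(table(factor(cls, levels = c(
    "H_like_dimer", "J_like_dimer", "H_like_separated", "J_like_separated"))))
  out <- list(config_hash = config_hash(config),
              thresholds = list(kappa_boundary = a$kappa_boundary,
                                dimer_r_max_nm = a$dimer_r_max_nm),
              n_trials = summ$n_trials, n_observations = summ$n_observations,
              quantities = summ$quantities, classification = tal)
  jsonlite::write_json(out, paste0(out_prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}

#' Run the contact-map stage
#'
#' Builds the residue groups (centre window plus dyes), computes one
#' contact map per trial at the contact stride and pools them by frame
#' count into `<prefix>_contacts.tsv` (plus the long-format companion).
#'
#' @inheritParams pipeline_analyze
#' @return The pooled `contact_map`, invisibly.
#' @export
pipeline_contacts <- function(config, out_prefix) {
  trials <- load_trials(config)
  a <- config$analysis
  w <- a$window
  groups <- build_groups(trials[[1]]$topology, config$dyes %||% list(),
                         center_window = seq(w[1], w[2]))
  maps <- lapply(trials, contact_map, groups = groups, cutoff = a$cutoff_nm,
                 stride = a$contact_stride_ps, burn_in = a$burn_in_ps)
  pooled <- pool_contact_maps(maps)
  write_contact_map(pooled, paste0(out_prefix, "_contacts.tsv"),
                    meta = c(config_hash = config_hash(config)))
  invisible(pooled)
}

#' Run the heatmap stage
#'
#' Recomputes pooled observations and writes the normalized 2-D
#' histogram of |kappa| versus R (`<prefix>_heatmap_kappa.tsv`) and, when
#' couplings are available, of |J| versus R (`<prefix>_heatmap_J.tsv`).
#'
#' @inheritParams pipeline_analyze
#' @return list of `dimer_histogram`s, invisibly.
#' @export
pipeline_heatmap <- function(config, out_prefix) {
  trials <- load_trials(config)
  if (length(config$dyes %||% list()) != 2L)
    user_error("configuration error: heatmap needs exactly two dyes")
  a <- config$analysis; b <- config$bins
  obs <- lapply(trials, observe_dimer, dye_m = config$dyes[[1]],
                dye_n = config$dyes[[2]], stride = a$stride_ps,
                burn_in = a$burn_in_ps, coupling = config$coupling_cfg)
  r_breaks <- seq(0, b$r_max_nm, by = b$r_width_nm)
  hk <- dimer_heatmap(obs, y = "abs_kappa", r_breaks = r_breaks,
                      y_breaks = seq(0, 2, by = b$kappa_width))
  write_heatmap(hk, paste0(out_prefix, "_heatmap_kappa.tsv"),
                meta = c(config_hash = config_hash(config)))
  out <- list(kappa = hk)
  if ("abs_J" %in% names(obs[[1]])) {
    hj <- dimer_heatmap(obs, y = "abs_J", r_breaks = r_breaks,
                        y_breaks = seq(0, b$j_max_mev, by = b$j_width_mev))
    write_heatmap(hj, paste0(out_prefix, "_heatmap_J.tsv"),
                  meta = c(config_hash = config_hash(config)))
    out$J <- hj
  }
  invisible(out)
}

expand_span <- function(span) seq(span[[1]], span[[2]])

config_arm <- function(x) {
  arm_definition(x$label %||% "arm", chain1 = x$chain1,
                 resnos1 = expand_span(x$resnos1),
                 chain2 = x$chain2, resnos2 = expand_span(x$resnos2))
}

#' Run the junction-angle stage
#'
#' Computes the inter-duplex and twist angle time series from the
#' `junction` config section (two duplexes, each two arms given as
#' `{chain1, resnos1: [from, to], chain2, resnos2: [from, to]}`), written
#' as `<prefix>_angles.tsv`.
#'
#' @inheritParams pipeline_analyze
#' @return The angle data.frame, invisibly.
#' @export
pipeline_junction <- function(config, out_prefix) {
  if (is.null(config$junction))
    user_error("configuration error: junction section required")
  trials <- load_trials(config)
  a <- config$analysis
  d1 <- lapply(config$junction$duplex1, config_arm)
  d2 <- lapply(config$junction$duplex2, config_arm)
  ser <- do.call(rbind, lapply(trials, junction_angle_series, duplex1 = d1,
                               duplex2 = d2, stride = a$stride_ps,
                               burn_in = a$burn_in_ps))
  path <- paste0(out_prefix, "_angles.tsv")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(output_header(config), "time\tida_deg\ttwist_deg"), con)
  writeLines(sprintf("%.8g\t%.8g\t%.8g", ser$time, ser$ida_deg,
                     ser$twist_deg), con)
  invisible(ser)
}

#' Run the synthetic-generation stage
#'
#' Driven by the `synth` config section.  `kind: dimer` generates a
#' rigid-rod ensemble from a [synthetic_spec()] built from the section's
#' fields; `kind: junction` generates a mock junction.  Writes the
#' trajectory both as multi-model PDB (`<prefix>_synth.pdb`) and plain
#' frames (`<prefix>_synth.frames`), plus the ground-truth sidecar
#' (`<prefix>_ground_truth.jsonl`).
#'
#' @inheritParams pipeline_analyze
#' @param seed optional override of the config's seed.
#' @return The generator's result list, invisibly.
#' @export
pipeline_synth <- function(config, out_prefix, seed = NULL) {
  s <- config$synth
  if (is.null(s)) user_error("configuration error: synth section required")
  kind <- s$kind %||% "dimer"
  if (!is.null(seed)) s$seed <- seed
  gen <- if (kind == "dimer") {
    spec <- synthetic_spec(mode = s$mode %||% "H_dimer",
                           n_frames = s$n_frames %||% 3000,
                           dt = s$dt %||% 100, seed = s$seed %||% 1,
                           r_mean = s$r_mean, r_sd = s$r_sd,
                           angle_sd_deg = s$angle_sd_deg %||% 10,
                           l_m = s$l_m %||% 1.4, l_n = s$l_n %||% 1.4,
                           weights = unlist(s$weights))
    generate_dimer_trajectory(spec)
  } else if (kind == "junction") {
    generate_mock_junction(isomer = s$isomer %||% "IsoI",
                           attachment = s$attachment %||% "transverse",
                           n_frames = s$n_frames %||% 100,
                           seed = s$seed %||% 1,
                           ida_deg = s$ida_deg %||% 60,
                           dt = s$dt %||% 500,
                           jitter_sd = s$jitter_sd %||% 0)
  } else user_error("configuration error: synth kind must be dimer or junction")
  write_trajectory(gen$trajectory, paste0(out_prefix, "_synth.pdb"), "pdb")
  write_trajectory(gen$trajectory, paste0(out_prefix, "_synth.frames"),
                   "frames")
  write_ground_truth(gen$ground_truth,
                     paste0(out_prefix, "_ground_truth.jsonl"))
  invisible(gen)
}

cli_usage <- function() {
  paste(
    "usage: hjdimer <analyze|contacts|heatmap|junction|synth>",
    "--config FILE --out-prefix PREFIX [--log-level LEVEL] [--seed N]",
    sep = " ")
}

parse_cli_args <- function(args) {
  if (!length(args)) user_error(cli_usage())
  cmd <- args[1]; args <- args[-1]
  opt <- list(log_level = "info")
  i <- 1
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args))
      user_error("configuration error: bad argument '", key, "'. ", cli_usage())
    val <- args[i + 1]
    opt[[gsub("-", "_", substring(key, 3))]] <- val
    i <- i + 2
  }
  opt$cmd <- cmd
  opt
}

#' Command-line entry point
#'
#' Dispatches the subcommands `analyze`, `contacts`, `heatmap`,
#' `junction` and `synth` over the pipeline functions.  Log messages go
#' to stderr; numeric results only to the output files.  Returns 0 on
#' success, 1 on configuration/input errors, 2 on internal errors.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status.
#' @export
run_cli <- function(args) {
  logmsg <- function(...) message("[hjdimer] ", ...)
  tryCatch({
    opt <- parse_cli_args(args)
    if (!opt$cmd %in% c("analyze", "contacts", "heatmap", "junction", "synth"))
      user_error("configuration error: unknown subcommand '", opt$cmd, "'. ",
                 cli_usage())
    if (is.null(opt$config) || is.null(opt$out_prefix))
      user_error("configuration error: --config and --out-prefix are required")
    config <- read_run_config(opt$config)
    if (opt$log_level != "quiet")
      logmsg("running ", opt$cmd, " (config ", config_hash(config), ")")
    switch(opt$cmd,
           analyze = pipeline_analyze(config, opt$out_prefix),
           contacts = pipeline_contacts(config, opt$out_prefix),
           heatmap = pipeline_heatmap(config, opt$out_prefix),
           junction = pipeline_junction(config, opt$out_prefix),
           synth = pipeline_synth(config, opt$out_prefix,
                                  seed = if (!is.null(opt$seed))
                                    as.integer(opt$seed)))
    if (opt$log_level != "quiet") logmsg("done")
    0L
  },
  hj_user_error = function(e) { message("[hjdimer] error: ",
                                        conditionMessage(e)); 1L },
  error = function(e) {
    msg <- conditionMessage(e)
    user_like <- grepl(paste0("^(configuration|format|metadata|selection|",
                              "topology|analysis|frame-consistency|",
                              "degenerate-geometry|geometry) error"), msg)
    message("[hjdimer] ", if (user_like) "error: " else "internal error: ", msg)
    if (user_like) 1L else 2L
  })
}
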