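# Replica-averaging convention, human-readable formatting and the
# multi-model pipeline orchestrator.

#' Replica mean and standard error
#'
#' Properties are evaluated separately per independent replica and then
#' averaged; the standard error of that mean (sample SD / sqrt(n)) is the
#' error estimate.  With a single replica the SE is not available.
#'
#' @param values numeric vector, one value per replica.
#' @return List: \code{mean}, \code{se} (\code{NA} when \code{n = 1}),
#'   \code{n}.
#' @export
replica_average <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("need at least one replica value")
  n <- length(values)
  list(mean = mean(values),
       se = if (n == 1) NA_real_ else sd(values) / sqrt(n),
       n = n)
}

#' Format a mean and error in "19.6 +/- 0.9" style
#'
#' @param mean,se numbers.
#' @param digits decimal places (default 1).
#' @export
format_pm <- function(mean, se, digits = 1) {
  if (is.na(se))
    sprintf("%.*f (single replica)", digits, mean)
  else
    sprintf("%.*f ± %.*f", digits, mean, digits, se)
}

#' Run the full synthetic analysis pipeline for a set of models
#'
#' For each protonation-model code, generates (or loads) the per-replica
#' trajectories, discards equilibration, runs the water census, the
#' residue-water hydrogen-bond statistics and lifetimes on the probe
#' residues, and the water-mediated connectivity, and writes tidy CSV
#' tables plus a machine-readable run manifest.
#'
#' @param config list (or YAML file path) with elements: \code{models}
#'   (codes or wildcard patterns), \code{n_replicas}, \code{seed},
#'   \code{equil_ns}, \code{out_dir}, and optionally any
#'   \code{\link{synthetic_channel_spec}} argument under \code{synth}.
#' @return Invisibly, a list of the result tables; CSVs and
#'   \code{manifest.json} are written to \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$models), !is.null(config$out_dir))
  models <- unique(unlist(lapply(config$models, function(m)
    if (grepl("\\*", m))
      vapply(expand_wildcard(m), `[[`, "", "code")
    else format_model_code(parse_model_code(m)))))
  n_rep <- if (is.null(config$n_replicas)) 3L else config$n_replicas
  seed <- if (is.null(config$seed)) 1L else config$seed
  equil_ns <- if (is.null(config$equil_ns)) 0 else config$equil_ns
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character(0)
  census_rows <- list(); hb_rows <- list(); life_rows <- list()
  net_rows <- list()
  for (m in models) {
    pm <- parse_model_code(m)
    per_rep_census <- list(); per_rep_net <- list()
    for (r in seq_len(n_rep)) {
      sargs <- config$synth
      if (is.null(sargs)) sargs <- list()
      sargs$hydronium <- if (is.na(pm$hydronium_position)) NA_character_
      else pm$hydronium_position
      sargs$seed <- seed + 1000L * match(m, models) + r
      if (is.null(sargs$probes))
        sargs$probes <- data.frame(label = "probe1", k_on = 1 / 60,
                                   k_off = 1 / 30)
      sys <- do.call(synthetic_channel_spec, sargs)
      sys <- generate_system(sys)
      traj <- discard_equilibration(sys$traj, equil_ns)
      hyd <- water_census(traj, sys$channel)
      per_rep_census[[r]] <- hyd

      # probe H-bond stats + lifetime
      probes <- sys$spec$probes
      for (k in seq_len(nrow(probes))) {
        ser <- residue_water_hbond_stats(
          traj, data.frame(chain = "P", resid = 1000 + k))
        hb_rows[[length(hb_rows) + 1]] <-
          data.frame(model = m, replica = r, probe = probes$label[k],
                     mean_bonds = ser$mean_count,
                     bond_probability = ser$probability)
        ac <- tryCatch(hbond_autocorrelation(ser), error = function(e) NULL)
        if (!is.null(ac)) {
          lf <- fit_lifetime(ac)
          life_rows[[length(life_rows) + 1]] <-
            data.frame(model = m, replica = r, probe = probes$label[k],
                       A = lf$A, tau1 = lf$tau1, B = lf$B, tau2 = lf$tau2,
                       tau = lf$tau, determined = lf$determined)
        } else {
          warnings_log <- c(warnings_log, sprintf(
            "model %s replica %d probe %s: no bonded origin", m, r,
            probes$label[k]))
        }
      }

      # connectivity between probe residues via waters (toy network)
      kr <- data.frame(chain = "P", resid = 1000 + seq_len(nrow(probes)),
                       label = probes$label)
      ev <- channel_frame_events(traj, kr)
      if (nrow(probes) >= 2) {
        per_rep_net[[r]] <- connection_probability(ev, kr$label)
      }
    }
    prof <- height_profile(per_rep_census)
    for (s in seq_len(nrow(prof)))
      census_rows[[length(census_rows) + 1]] <-
        data.frame(model = m, slice = prof$slice[s], height = prof$height[s],
                   mean = prof$mean[s], se = prof$se[s])
    counts <- vapply(per_rep_census, function(h) mean(h$frame_counts),
                     numeric(1))
    st <- replica_average(counts)
    census_rows[[length(census_rows) + 1]] <-
      data.frame(model = m, slice = NA_integer_, height = NA_real_,
                 mean = st$mean, se = st$se)
    if (length(per_rep_net))
      net_rows[[length(net_rows) + 1]] <-
        cbind(model = m, connection_probability_summary(per_rep_net))
  }

  out <- list(
    census = do.call(rbind, census_rows),
    hbonds = do.call(rbind, hb_rows),
    lifetimes = if (length(life_rows)) do.call(rbind, life_rows) else NULL,
    network = if (length(net_rows)) do.call(rbind, net_rows) else NULL)
  write.csv(out$census, file.path(config$out_dir, "water_census.csv"),
            row.names = FALSE)
  write.csv(out$hbonds, file.path(config$out_dir, "hbond_stats.csv"),
            row.names = FALSE)
  if (!is.null(out$lifetimes))
    write.csv(out$lifetimes, file.path(config$out_dir, "hbond_lifetimes.csv"),
              row.names = FALSE)
  if (!is.null(out$network))
    write.csv(out$network, file.path(config$out_dir, "connectivity.csv"),
              row.names = FALSE)
  manifest <- list(models = models, n_replicas = n_rep, seed = seed,
                   equil_ns = equil_ns,
                   package_version = as.character(
                     utils::packageVersion("channelflow")),
                   parameters = list(
                     hbond = unclass(hbond_criterion()),
                     cylinder = list(radius = 9.5, n_slices = 15,
                                     slice_thickness = 2,
                                     elongation = 0.10)),
                   warnings = warnings_log,
                   timestamp_order = "deterministic under fixed seed")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
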