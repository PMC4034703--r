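TRAJ_SCHEMA <- "vfgn-trajectory/1"

fmt_num <- function(x) {
  # full precision: round-trips doubles exactly through text
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

#' Write a trajectory log
#'
#' One CSV per trial: a commented header block (schema version, units,
#' arena and goal geometry, start, pointed azimuth, flags) followed by
#' columns `t,x,y,post_reveal`.  Coordinates are serialized at full
#' precision so the round trip is exact.  A JSON sidecar
#' (`<path sans .csv>.json`) carries the phase trace and the same metadata
#' in structured form.
#'
#' @param traj A `vfgn_trajectory`.
#' @param path Output CSV path.
#' @param trace Optional phase-trace list (from [run_trial()]).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, trace = NULL) {
  stopifnot(inherits(traj, "vfgn_trajectory"))
  hdr <- c(
    paste0("# schema: ", TRAJ_SCHEMA),
    "# units: meters, seconds, degrees (azimuth CCW from +x, origin at arena center)",
    paste0("# arena_radius: ", fmt_num(traj$arena$radius)),
    paste0("# goal_x: ", fmt_num(traj$goal$center[1])),
    paste0("# goal_y: ", fmt_num(traj$goal$center[2])),
    paste0("# goal_radius: ", fmt_num(traj$goal$radius)),
    paste0("# goal_active: ", traj$goal$active),
    paste0("# goal_visible: ", traj$goal$visible),
    paste0("# start_x: ", fmt_num(traj$start[1])),
    paste0("# start_y: ", fmt_num(traj$start[2])),
    paste0("# pointed_azimuth: ", fmt_num(traj$pointed_azimuth)),
    paste0("# dt: ", fmt_num(traj$dt)),
    paste0("# search_limit: ", fmt_num(traj$search_limit)),
    paste0("# found: ", traj$found),
    paste0("# entry_time: ", fmt_num(traj$entry_time)),
    paste0("# reveal: ", traj$reveal),
    paste0("# trial_index: ", traj$trial_index),
    paste0("# phase_label: ", traj$phase_label),
    paste0("# goal_id: ", traj$goal_id))
  body <- paste(fmt_num(traj$samples$t), fmt_num(traj$samples$x),
                fmt_num(traj$samples$y),
                as.integer(traj$samples$post_reveal), sep = ",")
  writeLines(c(hdr, "t,x,y,post_reveal", body), path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(schema = TRAJ_SCHEMA, trial_index = traj$trial_index,
               phase_label = traj$phase_label, goal_id = traj$goal_id,
               pointed_azimuth = traj$pointed_azimuth,
               found = traj$found, reveal = traj$reveal,
               entry_time = traj$entry_time,
               trace = trace)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^# ", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- sub("^[^:]*: ?", "", kv)
  stats::setNames(as.list(vals), keys)
}

num_or_na <- function(x) {
  if (is.null(x) || x == "NA") NA_real_ else as.numeric(x)
}

#' Read a trajectory log
#'
#' Parses the CSV dialect written by [write_trajectory()].  Files with a
#' different schema version are rejected (the error names both versions);
#' non-monotone time stamps are rejected with the offending row number;
#' legacy files lacking the `post_reveal` column are accepted with the
#' column defaulted to `FALSE` and a warning.
#'
#' @param path CSV path; a same-stem `.json` sidecar is merged when present.
#' @return A `vfgn_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- parse_header(lines[is_hdr])
  if (is.null(hdr$schema) || hdr$schema != TRAJ_SCHEMA) {
    stop(sprintf("schema version mismatch: file has %s, reader expects %s",
                 if (is.null(hdr$schema)) "<none>" else hdr$schema,
                 TRAJ_SCHEMA))
  }
  body <- lines[!is_hdr]
  cols <- strsplit(body[1], ",")[[1]]
  dat <- read.csv(text = paste(body, collapse = "\n"))
  if (!"post_reveal" %in% names(dat)) {
    warning("legacy trajectory file without post_reveal column; ",
            "defaulting to FALSE")
    dat$post_reveal <- 0L
  }
  bad <- which(diff(dat$t) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-monotone time stamps at data row %d", bad[1] + 1L))
  }
  samples <- data.frame(t = dat$t, x = dat$x, y = dat$y,
                        post_reveal = as.logical(dat$post_reveal))
  arena <- arena_spec(as.numeric(hdr$arena_radius))
  goal <- goal_spec(c(as.numeric(hdr$goal_x), as.numeric(hdr$goal_y)),
                    as.numeric(hdr$goal_radius),
                    active = as.logical(hdr$goal_active),
                    visible = as.logical(hdr$goal_visible))
  new_trajectory(samples,
                 start = c(as.numeric(hdr$start_x), as.numeric(hdr$start_y)),
                 pointed_azimuth = num_or_na(hdr$pointed_azimuth),
                 dt = as.numeric(hdr$dt), goal = goal, arena = arena,
                 found = as.logical(hdr$found),
                 entry_time = num_or_na(hdr$entry_time),
                 search_limit = as.numeric(hdr$search_limit),
                 reveal = as.logical(hdr$reveal),
                 trial_index = suppressWarnings(as.integer(hdr$trial_index)),
                 phase_label = hdr$phase_label, goal_id = hdr$goal_id)
}

#' Write / read a session configuration
#'
#' The configuration file (YAML) captures everything needed to rebuild a
#' session: schema version, protocol, arena radius, cue layout, goal
#' positions, goal radius and the seed.  All angles are degrees, lengths
#' meters, times seconds.
#'
#' @param session A `vfgn_session`.
#' @param path Output YAML path.
#' @return `path` invisibly (writer); a rebuilt `vfgn_session` (reader).
#' @export
write_session_config <- function(session, path) {
  stopifnot(inherits(session, "vfgn_session"))
  cfg <- list(
    schema = "vfgn-session/1",
    units = "meters, seconds, degrees (azimuth CCW from +x)",
    protocol = session$protocol,
    arena_radius = session$arena$radius,
    goal_radius = session$trials[[1]]$goal$radius,
    goal_positions = lapply(session$goal_positions, as.numeric),
    cues = lapply(seq_len(nrow(session$cue_set)), function(i) {
      list(id = session$cue_set$id[i], x = session$cue_set$x[i],
           y = session$cue_set$y[i])
    }),
    seed = session$seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || cfg$schema != "vfgn-session/1") {
    stop(sprintf("schema version mismatch: file has %s, reader expects %s",
                 if (is.null(cfg$schema)) "<none>" else cfg$schema,
                 "vfgn-session/1"))
  }
  arena <- arena_spec(cfg$arena_radius)
  cue_az <- vapply(cfg$cues, function(cc) azimuth(c(cc$x, cc$y)), numeric(1))
  cue_r <- vapply(cfg$cues, function(cc) sqrt(cc$x^2 + cc$y^2), numeric(1))
  cues <- cue_set(arena, azimuths = cue_az,
                  radius_frac = mean(cue_r) / arena$radius,
                  ids = vapply(cfg$cues, `[[`, character(1), "id"))
  if (cfg$protocol == "rm") {
    build_rm_session(arena, cues,
                     goal_pos = as.numeric(cfg$goal_positions$RM),
                     goal_radius = cfg$goal_radius, seed = cfg$seed)
  } else {
    build_dmp_session(arena, cues,
                      goal_positions = lapply(cfg$goal_positions, as.numeric),
                      goal_radius = cfg$goal_radius, seed = cfg$seed)
  }
}

#' Write / read an agent configuration
#'
#' @param params A `vfgn_agent_params`.
#' @param path YAML path.
#' @return `path` invisibly (writer); a `vfgn_agent_params` (reader).
#' @export
write_agent_config <- function(params, path) {
  stopifnot(inherits(params, "vfgn_agent_params"))
  yaml::write_yaml(c(list(schema = "vfgn-agent/1"),
                     unclass(params)[!vapply(unclass(params), is.null,
                                             logical(1))]),
                   path)
  invisible(path)
}

#' @rdname write_agent_config
#' @export
read_agent_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || cfg$schema != "vfgn-agent/1") {
    stop(sprintf("schema version mismatch: file has %s, reader expects %s",
                 if (is.null(cfg$schema)) "<none>" else cfg$schema,
                 "vfgn-agent/1"))
  }
  agent_params(pointing_sd = cfg$pointing_sd, memory_sd0 = cfg$memory_sd0,
               memory_decay = cfg$memory_decay, forget_sd = cfg$forget_sd,
               heading_sd = cfg$heading_sd, lapse_rate = cfg$lapse_rate,
               seed = cfg$seed)
}

#' Write a run manifest
#'
#' Records the schema version, seeds, file inventory and MD5 checksums of a
#' run directory so that any output can be verified and reproduced.
#'
#' @param dir Run directory.
#' @param seeds Named list of seeds used.
#' @param files Character vector of file paths (relative to `dir`).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, seeds, files) {
  paths <- file.path(dir, files)
  stopifnot(all(file.exists(paths)))
  manifest <- list(
    schema = "vfgn-manifest/1",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    files = lapply(seq_along(files), function(i) {
      list(path = files[i], md5 = unname(tools::md5sum(paths[i])))
    }))
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Verify a run manifest
#'
#' @param dir Run directory containing `manifest.json`.
#' @return `TRUE` invisibly; errors on a missing file or checksum mismatch.
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  for (f in manifest$files) {
    p <- file.path(dir, f$path)
    if (!file.exists(p)) stop("manifest references missing file: ", f$path)
    if (unname(tools::md5sum(p)) != f$md5) {
      stop("checksum mismatch for ", f$path)
    }
  }
  invisible(TRUE)
}

#' Generate the bundled miniature dataset
#'
#' Deterministically simulates one RM and one DMP session for four agents
#' (two per shipped preset), writes every trajectory log, a tidy metrics
#' CSV (one row per subject, session, trial and metric) and a manifest.
#' Used by the test suite and the documentation examples.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces the bundle
#'   byte-for-byte (the manifest's timestamp aside).
#' @return Invisibly, a list with the cohort table (`metrics`) and the
#'   manifest path.
#' @export
generate_fixtures <- function(dir, seed = 20140527) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  cohort <- make_cohort(list(HC = preset_params("healthy_like"),
                             SZ = preset_params("impaired_like")),
                        n_per_group = 2, cv = 0.2)
  arena <- arena_spec()
  kin <- kinematics()
  files <- character(0)
  metrics <- list()
  for (subj in cohort) {
    policy <- memory_navigator(subj$params, arena)
    for (pr in c("rm", "dmp")) {
      session <- if (pr == "rm") build_rm_session(arena) else
        build_dmp_session(arena, cues = cue_set(
          arena, ids = c("dmp1", "dmp2", "dmp3")))
      trajs <- run_session(session, policy, kin)
      for (i in seq_along(trajs)) {
        fn <- sprintf("%s_%s_trial%02d.csv", subj$subject_id, pr, i)
        write_trajectory(trajs[[i]], file.path(dir, fn))
        files <- c(files, fn, sub("\\.csv$", ".json", fn))
      }
      sc <- score_session(session, trajs)$trials
      sc$subject_id <- subj$subject_id
      sc$group <- subj$group
      sc$session <- pr
      metrics[[length(metrics) + 1L]] <- sc
    }
  }
  mtab <- do.call(rbind, metrics)
  mpath <- file.path(dir, "metrics.csv")
  write.csv(mtab, mpath, row.names = FALSE)
  files <- c(files, "metrics.csv")
  write_manifest(dir, seeds = list(master = seed), files = files)
  invisible(list(metrics = mtab, manifest = file.path(dir, "manifest.json")))
}
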