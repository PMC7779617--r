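#' Pipeline configuration
#'
#' All stage parameters in one validated list. The defaults are the
#' desk-scale demo profile (8 channels, 30 thresholds); `profile =
#' "full"` switches to the clinical-scale settings (16 channels, 600
#' thresholds over (0, 0.006], core 8x6x2x2x4).
#'
#' @param ... Named overrides of any default field.
#' @param profile `"demo"` (default) or `"full"`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., profile = c("demo", "full")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    # synthetic cohort
    subjects_per_group = if (profile == "demo") 20L else 50L,
    channels = if (profile == "demo") 8L else 16L,
    fs = 256, duration = 20, noise_sd = 1, coupling_strength = 0.4,
    # preprocessing
    fs_out = 256, seg_seconds = 20, rhythm_backend = "butter", notch = TRUE,
    # transfer entropy
    te_d = 1L, te_m = 1L, te_tau = 1L, te_u = 1L, te_bins = 8L,
    segment_aggregate = "mean",
    # thresholds; the demo grid spans the transfer-entropy range of the
    # synthetic cohorts (bias floor ~0.06 bits up to coupling-driven ~0.4),
    # the full grid is the clinical-scale sweep
    grid_start = 0,
    grid_stop = if (profile == "demo") 0.45 else 0.006,
    grid_step = if (profile == "demo") 0.015 else 1e-5,
    # Tucker core
    core_shape = if (profile == "demo") c(6L, 4L, 2L, 2L, 4L)
                 else c(8L, 6L, 2L, 2L, 4L),
    hooi_max_iter = 50L, hooi_tol = 1e-6,
    # classifier
    kernel = "medium_gaussian", folds = 10L, repeats = 20L, cost = 1,
    positive = NULL,
    seed = 1L)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Vector values (e.g. `core_shape`) are comma-separated. Unknown
#' keys are rejected.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- lapply(kv, function(x) parse_config_value(x[[2L]]))
  names(vals) <- keys
  do.call(pipeline_config, vals)
}

parse_config_value <- function(v) {
  parts <- trimws(strsplit(v, ",")[[1L]])
  num <- suppressWarnings(as.numeric(parts))
  out <- if (anyNA(num)) {
    lg <- toupper(parts)
    if (all(lg %in% c("TRUE", "FALSE"))) as.logical(lg) else parts
  } else {
    num
  }
  if (length(out) == 1L) out else out
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @return `write_config` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) return(NA_character_)
    sprintf("%s = %s", k, paste(v, collapse = ","))
  }, character(1))
  writeLines(fmt[!is.na(fmt)], path)
  invisible(path)
}

#' Run one pipeline stage (or the whole pipeline) into a run directory
#'
#' Dispatcher behind the command-line entry point. Each command reads its
#' inputs from `run_dir` (as written by the preceding stage), writes its
#' artifacts there, and appends the parameters used to
#' `run_dir/manifest_log.txt` so a run directory documents itself.
#'
#' Commands: `simulate` (synthetic cohort), `preprocess` (per-rhythm
#' segment files), `connect` (per-subject per-rhythm TE weight matrices),
#' `netbuild` (group t-test networks at a reference threshold), `imper`
#' (removal feature curves of those group networks), `tensorize`
#' (per-subject core vectors), `classify` (cross-validated report), and
#' `pipeline` (simulate + everything in memory + report).
#'
#' @param command Stage name.
#' @param cfg A `pipeline_config`.
#' @param run_dir Artifact directory (created if missing).
#' @return Invisibly, the main artifact of the stage.
#' @export
run_stage <- function(command = c("simulate", "preprocess", "connect",
                                  "netbuild", "imper", "tensorize",
                                  "classify", "pipeline"),
                      cfg = pipeline_config(), run_dir = "epitensor_run") {
  command <- match.arg(command)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(run_dir, command, cfg)
  out <- switch(command,
                simulate = stage_simulate(cfg, run_dir),
                preprocess = stage_preprocess(cfg, run_dir),
                connect = stage_connect(cfg, run_dir),
                netbuild = stage_netbuild(cfg, run_dir),
                imper = stage_imper(cfg, run_dir),
                tensorize = stage_tensorize(cfg, run_dir),
                classify = stage_classify(cfg, run_dir),
                pipeline = stage_pipeline(cfg, run_dir))
  invisible(out)
}

log_run <- function(run_dir, command, cfg) {
  line <- sprintf("[%s] %s  %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  command,
                  paste(sprintf("%s=%s", names(cfg),
                                vapply(cfg, function(v)
                                  paste(v, collapse = ","), character(1))),
                        collapse = " "))
  cat(line, "\n", file = file.path(run_dir, "manifest_log.txt"),
      append = TRUE)
}

cohort_from_cfg <- function(cfg) {
  spec <- cohort_spec(
    subjects_per_group = cfg$subjects_per_group, channels = cfg$channels,
    fs = cfg$fs, duration = cfg$duration,
    coupling_A = ring_coupling(cfg$channels, cfg$coupling_strength),
    coupling_B = hub_coupling(cfg$channels, cfg$coupling_strength),
    noise_sd = cfg$noise_sd, seed = cfg$seed)
  synth_cohort(spec)
}

stage_simulate <- function(cfg, run_dir) {
  cohort <- cohort_from_cfg(cfg)
  write_cohort(cohort, file.path(run_dir, "cohort"))
  cohort
}

stage_preprocess <- function(cfg, run_dir) {
  cohort <- read_cohort(file.path(run_dir, "cohort"))
  out_dir <- file.path(run_dir, "rhythms")
  dir.create(out_dir, showWarnings = FALSE)
  for (su in cohort) {
    prep <- preprocess_subject(su$signals, fs_out = cfg$fs_out,
                               seg_seconds = cfg$seg_seconds,
                               backend = cfg$rhythm_backend,
                               notch = cfg$notch)
    for (si in seq_along(prep$segments)) {
      for (b in names(rhythm_bands())) {
        f <- file.path(out_dir, sprintf("%s_seg%d_%s.csv", su$id, si, b))
        utils::write.csv(t(prep$segments[[si]][[b]]$data), f,
                         row.names = FALSE)
      }
    }
  }
  out_dir
}

stage_connect <- function(cfg, run_dir) {
  cohort <- read_cohort(file.path(run_dir, "cohort"))
  rh_dir <- file.path(run_dir, "rhythms")
  te_dir <- file.path(run_dir, "te")
  dir.create(te_dir, showWarnings = FALSE)
  p <- te_params(cfg$te_d, cfg$te_m, cfg$te_tau, cfg$te_u, cfg$te_bins)
  for (su in cohort) {
    segs <- read_subject_rhythms(rh_dir, su$id, cfg$fs_out)
    conn <- subject_connectivity(segs, p, aggregate = cfg$segment_aggregate)
    for (b in names(conn)) {
      write_weight_matrix(conn[[b]],
                          file.path(te_dir, sprintf("%s_%s.tsv", su$id, b)))
    }
  }
  te_dir
}

read_subject_rhythms <- function(rh_dir, id, fs) {
  files <- list.files(rh_dir, pattern = sprintf("^%s_seg\\d+_beta\\.csv$", id))
  n_seg <- length(files)
  if (!n_seg) stop(sprintf("no rhythm files for subject %s in %s", id,
                           rh_dir), call. = FALSE)
  lapply(seq_len(n_seg), function(si) {
    sets <- lapply(names(rhythm_bands()), function(b) {
      f <- file.path(rh_dir, sprintf("%s_seg%d_%s.csv", id, si, b))
      signal_set(t(as.matrix(utils::read.csv(f))), fs = fs)
    })
    names(sets) <- names(rhythm_bands())
    do.call(rhythm_set, sets)
  })
}

read_subject_te <- function(te_dir, id) {
  conn <- lapply(names(rhythm_bands()), function(b)
    read_weight_matrix(file.path(te_dir, sprintf("%s_%s.tsv", id, b))))
  names(conn) <- names(rhythm_bands())
  conn
}

stage_netbuild <- function(cfg, run_dir) {
  cohort <- read_cohort(file.path(run_dir, "cohort"))
  te_dir <- file.path(run_dir, "te")
  groups <- vapply(cohort, `[[`, character(1), "group")
  t_ref <- cfg$grid_stop / 2
  nets <- list()
  for (grp in unique(groups)) {
    ids <- vapply(cohort[groups == grp], `[[`, character(1), "id")
    for (b in names(rhythm_bands())) {
      ws <- lapply(ids, function(id) read_subject_te(te_dir, id)[[b]])
      g <- group_sample_network(ws, t_ref, alpha = 0.01)
      f <- file.path(run_dir, sprintf("groupnet_%s_%s.tsv", grp, b))
      write_digraph_matrix(g, f, threshold = t_ref)
      nets[[sprintf("%s_%s", grp, b)]] <- g
    }
  }
  nets
}

stage_imper <- function(cfg, run_dir) {
  files <- list.files(run_dir, pattern = "^groupnet_.*\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("run `netbuild` before `imper`", call. = FALSE)
  rows <- lapply(files, function(f) {
    lab <- sub("^groupnet_(.*)\\.tsv$", "\\1", basename(f))
    mat <- as.matrix(utils::read.table(f, skip = 2L))
    g <- binary_digraph(mat)
    do.call(rbind, lapply(c("receive", "send"), function(mode) {
      cv <- feature_curves(edge_removal_sequence(g, mode))
      cv$network <- lab
      cv
    }))
  })
  curves <- do.call(rbind, rows)
  utils::write.csv(curves, file.path(run_dir, "imper_curves.csv"),
                   row.names = FALSE)
  curves
}

stage_tensorize <- function(cfg, run_dir) {
  cohort <- read_cohort(file.path(run_dir, "cohort"))
  te_dir <- file.path(run_dir, "te")
  grid <- threshold_grid(cfg$grid_start, cfg$grid_stop, cfg$grid_step)
  rows <- lapply(cohort, function(su) {
    conn <- read_subject_te(te_dir, su$id)
    q <- build_feature_tensor(conn, grid)
    tk <- tucker_hooi(q, cfg$core_shape, max_iter = cfg$hooi_max_iter,
                      tol = cfg$hooi_tol)
    c(list(id = su$id, group = su$group, psi = tk$fit),
      as.list(stats::setNames(reshape_core(tk),
                              paste0("f", seq_len(prod(cfg$core_shape))))))
  })
  vec <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(vec, file.path(run_dir, "core_vectors.csv"),
                   row.names = FALSE)
  vec
}

stage_classify <- function(cfg, run_dir) {
  vec <- utils::read.csv(file.path(run_dir, "core_vectors.csv"),
                         stringsAsFactors = FALSE)
  feats <- as.matrix(vec[, grep("^f\\d+$", names(vec)), drop = FALSE])
  report <- cross_validate(feats, vec$group, kernel = cfg$kernel,
                           k = cfg$folds, repeats = cfg$repeats,
                           positive = cfg$positive, cost = cfg$cost,
                           seed = cfg$seed)
  df <- data.frame(kernel = report$kernel, t(report$counts),
                   t(report$metrics))
  utils::write.csv(df, file.path(run_dir, "report.csv"), row.names = FALSE)
  report
}

stage_pipeline <- function(cfg, run_dir) {
  cohort <- cohort_from_cfg(cfg)
  write_cohort(cohort, file.path(run_dir, "cohort"))
  res <- end_to_end(cohort, cfg)
  df <- data.frame(kernel = res$report$kernel, t(res$report$counts),
                   t(res$report$metrics), mean_psi = res$mean_psi)
  utils::write.csv(df, file.path(run_dir, "report.csv"), row.names = FALSE)
  write_config(cfg, file.path(run_dir, "config_used.cfg"))
  res
}
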