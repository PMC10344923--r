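#' Load a run configuration file
#'
#' Reads a structured YAML configuration with sections `rods`, `bead`,
#' `pattern` and `run`, validates every field against the type invariants,
#' and resolves the swimmer count: exactly one of `run$N` and `run$phi`
#' must be present.
#'
#' @param path path to a YAML file
#' @return list with elements `config` ([sim_config()]), `rod`
#'   ([rod_params()]), `bead` ([bead_spec()] or `NULL`) and `pattern`
#'   ([speed_pattern()])
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  y <- yaml::read_yaml(path)
  for (sec in c("pattern", "run"))
    if (is.null(y[[sec]])) stop("load_config: missing section '", sec, "'")

  r <- y$rods
  rod <- rod_params(
    ell = r$ell %||% 1, sigma = r$sigma %||% 0.5,
    alpha = r$alpha %||% 0.1, gamma = r$gamma %||% 1,
    gamma_rot = r$gamma_rot %||% ((r$gamma %||% 1) * (r$ell %||% 1)^2 / 12),
    k_rep = r$k_rep %||% 100)

  bead <- NULL
  if (!is.null(y$bead)) {
    b <- y$bead
    if (is.null(b$a)) stop("load_config: bead section must give the radius a")
    bead <- bead_spec(a = b$a,
                      center = if (!is.null(b$center)) unlist(b$center),
                      gamma_bead = b$gamma_bead %||% (2 * b$a),
                      mobile = b$mobile %||% TRUE)
  }

  p <- y$pattern
  for (f in c("v_minus", "v_plus", "v_zero"))
    if (is.null(p[[f]])) stop("load_config: pattern field '", f, "' missing")
  pattern <- speed_pattern(
    v_minus = p$v_minus, v_plus = p$v_plus, v_zero = p$v_zero,
    R = p$R %||% 1, delta = p$delta %||% 0,
    axis = if (!is.null(p$axis)) unlist(p$axis) else c(1, 0),
    type = p$type %||% "disc")

  ru <- y$run
  if (is.null(ru$L)) stop("load_config: run field 'L' missing")
  # a bare `N:` key is read as the YAML-1.1 boolean FALSE; accept it and the
  # explicit spelling `n_swimmers`
  n_sw <- ru$n_swimmers %||% ru$N %||% ru[["FALSE"]]
  if (is.null(n_sw) == is.null(ru$phi))
    stop("load_config: give exactly one of run$N and run$phi")
  config <- sim_config(
    L = ru$L, phi = ru$phi, N = n_sw, dt = ru$dt %||% 2e-3,
    n_steps = ru$n_steps %||% 1000L,
    save_every = ru$save_every %||% 100L,
    feedback_every = ru$feedback_every %||% 1L,
    interactions_on = ru$interactions_on %||% TRUE,
    transient_fraction = ru$transient_fraction %||% 0.2,
    rod = rod)

  list(config = config, rod = rod, bead = bead, pattern = pattern)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory archive
#'
#' Round-trip serialization of an `rt_traj` (native serialization with a
#' format-version tag; the version is checked on read).
#'
#' @param traj an `rt_traj`
#' @param path output path
#' @return `path` (write) or the trajectory (read)
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rt_traj"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  if (!inherits(traj, "rt_traj"))
    stop("read_trajectory: not a trajectory archive")
  if (!identical(traj$format_version, 1L))
    stop("read_trajectory: unsupported format version ",
         traj$format_version)
  traj
}

#' Write / read a field map archive
#'
#' @param fm a [field_map()]
#' @param path output path
#' @return `path` (write) or the field map (read)
#' @export
write_field_map <- function(fm, path) {
  stopifnot(inherits(fm, "field_map"))
  saveRDS(fm, path)
  invisible(path)
}

#' @rdname write_field_map
#' @export
read_field_map <- function(path) {
  fm <- readRDS(path)
  if (!inherits(fm, "field_map"))
    stop("read_field_map: not a field map archive")
  fm
}

#' Run manifest
#'
#' Reproducibility record for a run or a batch of runs: a hash of the
#' configuration, the seeds used, package version, timestamps and output
#' paths. Written next to each output by the analysis drivers.
#'
#' @param config any serializable configuration object
#' @param seeds integer vector of seeds
#' @param outputs character vector of output paths
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(config, seeds, outputs = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  structure(list(config_hash = unname(tools::md5sum(tf)),
                 seeds = seeds,
                 package_version = as.character(utils::packageVersion("activedrift")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 outputs = outputs),
            class = "run_manifest")
}

#' Write a manifest as YAML
#'
#' @param manifest a [run_manifest()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
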