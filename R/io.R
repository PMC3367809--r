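## Configuration files, result serialization and snapshot rendering.

.config_keys <- c(
  "model", "track", "reps", "seed", "max_steps", "cumulative",
  "n_leaders", "n_followers", "width", "height", "out", "params"
)
.param_keys <- c(
  "ldd", "fdd", "pos", "ats", "lmc", "fmc", "ppc", "frp", "lrp",
  "fmp", "lmp", "sid", "sip", "mdi", "mpi"
)

.config_dir <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) return(distal_biased_distribution(x))
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    return(directional_distribution(unlist(x)))
  }
  stop("config: ", what, " must be a distal-bias scalar or a direction -> probability map")
}

#' Load a run configuration from a YAML file
#'
#' The file names a model and optionally overrides defaults; directional
#' parameters are given either as a single distal-bias scalar or as a
#' direction -> probability map. Unknown keys, invalid probabilities and
#' out-of-range clock intervals are rejected with descriptive errors.
#'
#' Recognized top-level keys: `model` (required: ecm / contact / hybrid),
#' `track`, `reps`, `seed`, `max_steps`, `cumulative`, `n_leaders`,
#' `n_followers`, `width`, `height`, `out`, and a `params` block with any of
#' `ldd, fdd, pos, ats, lmc, fmc, ppc, frp, lrp, fmp, lmp, sid, sip, mdi,
#' mpi`.
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config`: list with the resolved `params` object and all
#'   run settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config: 'model' is required")
  model <- match.arg(cfg$model, c("ecm", "contact", "hybrid"))
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  p <- cfg$params
  if (!is.null(p)) {
    bad <- setdiff(names(p), .param_keys)
    if (length(bad)) {
      stop("config: unknown parameter(s): ", paste(bad, collapse = ", "))
    }
  }
  pget <- function(nm, def) if (is.null(p[[nm]])) def else p[[nm]]
  dget <- function(nm) {
    if (is.null(p[[nm]])) uniform_directional() else .config_dir(p[[nm]], nm)
  }
  track <- isTRUE(cfg$track %||% TRUE)
  params <- switch(model,
    ecm = ecm_params(
      ldd = dget("ldd"), fdd = dget("fdd"),
      pos = pget("pos", 0.5), ats = pget("ats", 0.5), track = track
    ),
    contact = contact_params(
      ldd = dget("ldd"), fdd = dget("fdd"),
      lmc = pget("lmc", 0.5), fmc = pget("fmc", 0.5),
      ppc = pget("ppc", 0.5), frp = pget("frp", 0.5),
      lrp = pget("lrp", 0.5), fmp = pget("fmp", 0.5),
      lmp = pget("lmp", 0.5), sid = pget("sid", FALSE),
      sip = pget("sip", FALSE), mdi = pget("mdi", 5), mpi = pget("mpi", 5)
    ),
    hybrid = hybrid_params(
      ldd = dget("ldd"), fdd = dget("fdd"),
      pos = pget("pos", 0.5), ats = pget("ats", 0.5),
      lmc = pget("lmc", 0.5), fmc = pget("fmc", 0.5),
      ppc = pget("ppc", 0.5), frp = pget("frp", 0.5),
      lrp = pget("lrp", 0.5), fmp = pget("fmp", 0.5),
      lmp = pget("lmp", 0.5), sid = pget("sid", FALSE),
      sip = pget("sip", FALSE), mdi = pget("mdi", 5), mpi = pget("mpi", 5),
      track = track
    )
  )
  structure(
    list(
      model = model,
      params = params,
      track = track,
      reps = as.integer(cfg$reps %||% 400L),
      seed = as.integer(cfg$seed %||% 1L),
      max_steps = as.integer(cfg$max_steps %||% 1000L),
      cumulative = isTRUE(cfg$cumulative %||% FALSE),
      n_leaders = as.integer(cfg$n_leaders %||% 3L),
      n_followers = as.integer(cfg$n_followers %||% 5L),
      width = as.integer(cfg$width %||% 150L),
      height = as.integer(cfg$height %||% 45L),
      out = cfg$out %||% "results"
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny stable rolling hash for manifest config fingerprints
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 268435456  # mod 2^28
  sprintf("%07x", as.integer(h))
}

#' Write replicate results to CSV files with a JSON manifest
#'
#' Writes the per-run table (`<prefix>_runs.csv`: replicate index, derived
#' seed stream, persistence, termination reason), the one-row summary
#' (`<prefix>_summary.csv`) and a machine-readable JSON manifest with the
#' flattened parameter set, master seed and a config hash -- everything
#' needed to regenerate the results exactly.
#'
#' @param summary A `replicate_summary` from [run_replicates()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths of the three files written.
#' @export
write_results <- function(summary, dir, prefix = "results") {
  stopifnot(inherits(summary, "replicate_summary"))
  if (is.null(summary$runs) || !nrow(summary$runs)) stop("no run records to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs_path <- file.path(dir, paste0(prefix, "_runs.csv"))
  summary_path <- file.path(dir, paste0(prefix, "_summary.csv"))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))

  runs <- summary$runs
  runs$master_seed <- summary$seed
  utils::write.csv(runs, runs_path, row.names = FALSE)
  utils::write.csv(as.data.frame(summary), summary_path, row.names = FALSE)

  ep <- .engine_params(summary$params)
  manifest <- list(
    package = "chainABM",
    version = as.character(utils::packageVersion("chainABM")),
    model = sub("_params$", "", summary$model),
    master_seed = summary$seed,
    n_replicates = summary$n,
    params = ep,
    config_hash = .config_hash(ep)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(runs = runs_path, summary = summary_path, manifest = manifest_path))
}

#' Render a simulation state snapshot
#'
#' Text mode draws one character per site (`#` Closed, `.` Open, `L` Leader,
#' `F` Follower); these rasters round-trip through [read_grid_raster()]
#' (agents read back as Occupied sites). PNG mode uses the conventional
#' colouring -- Closed grey, Open white, Followers blue, Leaders red -- and
#' draws extended filopodia as rays.
#'
#' @param record A [run_simulation()] result obtained with
#'   `return_state = TRUE`, or its `state` element.
#' @param path Output file; omit to just return the text raster.
#' @param format `"text"` or `"png"`.
#' @return Text raster lines, invisibly (text mode), or `path` (png mode).
#' @export
render_snapshot <- function(record, path = NULL, format = c("text", "png")) {
  format <- match.arg(format)
  state <- if (!is.null(record$state)) record$state else record
  if (is.null(state$grid) || is.null(state$agents)) {
    stop("no state to render; run the simulation with return_state = TRUE")
  }
  grid <- state$grid
  agents <- state$agents

  if (format == "text") {
    chars <- matrix(c("#", ".", ".")[grid$states + 1L], grid$width, grid$height)
    for (i in seq_len(nrow(agents))) {
      chars[agents$x[i] + 1L, agents$y[i] + 1L] <-
        if (agents$role[i] == "leader") "L" else "F"
    }
    lines <- apply(chars, 2, paste, collapse = "")
    if (!is.null(path)) writeLines(lines, path)
    return(invisible(lines))
  }

  if (is.null(path)) stop("png rendering needs an output path")
  grDevices::png(path, width = 6 * grid$width, height = 6 * grid$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  img <- matrix(0L, grid$width, grid$height)
  img[grid$states == SITE_OPEN] <- 1L
  graphics::image(
    seq_len(grid$width) - 1, seq_len(grid$height) - 1, img,
    col = c("grey55", "white"), zlim = c(0, 1),
    axes = FALSE, xlab = "", ylab = "", useRaster = TRUE
  )
  if (!is.null(state$protrusion_len)) {
    for (i in seq_len(nrow(agents))) {
      for (d in 1:8) {
        len <- state$protrusion_len[i, d]
        if (len > 0) {
          graphics::segments(
            agents$x[i], agents$y[i],
            agents$x[i] + len * .DX[d], agents$y[i] + len * .DY[d],
            col = "grey20", lwd = 1
          )
        }
      }
    }
  }
  graphics::points(
    agents$x, agents$y, pch = 15, cex = 1.4,
    col = ifelse(agents$role == "leader", "red3", "royalblue3")
  )
  invisible(path)
}
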