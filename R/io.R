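#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration with up to three blocks —
#' `pool`, `geometry` and `grid` — validates every field, fills defaults
#' for anything omitted, and rejects unknown keys. An empty file yields
#' the full default configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `pool` (a [mu_pool_config()]), `geometry` (a
#'   [muscle_geometry()]), and `grid` (levels, fractions, patterns,
#'   strategies, reps, master_seed).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known_blocks <- c("pool", "geometry", "grid")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  take <- function(block, allowed) {
    b <- raw[[block]]
    if (is.null(b)) b <- list()
    bad <- setdiff(names(b), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    b
  }
  pool_args <- take("pool", names(formals(mu_pool_config)))
  geom_args <- take("geometry", names(formals(muscle_geometry)))
  grid_defaults <- list(strategies = c("onion_skin", "reverse_onion_skin"),
                        patterns = c("none", "largest", "smallest",
                                     "unrestricted"),
                        fractions = c(0.2, 0.4, 0.6),
                        levels = seq(10, 100, by = 10),
                        reps = 10L, master_seed = 1L, with_emg = FALSE)
  grid_args <- take("grid", names(grid_defaults))
  grid <- utils::modifyList(grid_defaults, grid_args)
  list(pool = do.call(mu_pool_config, pool_args),
       geometry = do.call(muscle_geometry, geom_args),
       grid = grid)
}

#' Build a small test-scale pool
#'
#' Same generative rules at reduced size, for fast tests and examples.
#'
#' @param n_units number of units (>= 2).
#' @param total_fibers fiber total.
#' @param ... further arguments to [mu_pool_config()].
#' @return A `mu_pool` data frame.
#' @export
make_fixture_pool <- function(n_units = 12, total_fibers = 700, ...) {
  if (n_units < 2) stop("n_units must be >= 2", call. = FALSE)
  build_pool(mu_pool_config(n_units = n_units, total_fibers = total_fibers,
                            ...))
}

#' Write experiment results to disk
#'
#' Writes the trial table, the per-condition means, and a JSON run
#' manifest (resolved configuration, master seed, package version).
#' Re-running with identical inputs reproduces the CSVs byte for byte.
#'
#' @param grid a [run_grid()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_trials <- file.path(dir, "trials.csv")
  p_means <- file.path(dir, "condition_means.csv")
  p_manifest <- file.path(dir, "manifest.json")
  utils::write.csv(as.data.frame(grid), p_trials, row.names = FALSE)
  utils::write.csv(condition_means(grid), p_means, row.names = FALSE)
  cfg <- attr(grid, "config")
  manifest <- list(
    package = "mupool",
    version = as.character(utils::packageVersion("mupool")),
    master_seed = attr(grid, "master_seed"),
    n_trials = nrow(grid),
    config = unclass(cfg))
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(trials = p_trials, means = p_means, manifest = p_manifest))
}
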