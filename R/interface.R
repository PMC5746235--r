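#' Build a full run configuration
#'
#' A single document combining the mesh spec, model parameters, phase rule,
#' integrator settings and scenario choice, with all defaults equal to the
#' package's standard parameter tables.  Unknown keys are rejected.
#'
#' @param mesh named list of [mesh_spec()] arguments.
#' @param params named list of [default_params()] overrides.
#' @param phase named list of [phase_config()] arguments.
#' @param integrator named list of [integrator_config()] arguments.
#' @param scenario scenario name (see [make_scenario()]).
#' @param horizon simulation horizon.
#' @param output named list: `record_every`, `snapshot_times`.
#' @return A `run_config` object with all values resolved.
#' @export
run_config <- function(mesh = list(), params = list(), phase = list(),
                       integrator = list(), scenario = "mixed",
                       horizon = 20, output = list()) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key(s) in '", where, "': ", paste(bad, collapse = ", "))
    x
  }
  mesh <- check_keys(mesh, c("nx", "ny", "h", "d_x", "d_y", "seed"), "mesh")
  m <- utils::modifyList(list(nx = 64L, ny = 64L, h = 1, seed = 1L), mesh)
  if (is.null(m$d_x)) m$d_x <- 0.5 * m$h
  if (is.null(m$d_y)) m$d_y <- 0.5 * m$h
  spec <- do.call(mesh_spec, m)

  scenario <- match.arg(scenario, c("pv_only", "ec_only", "mixed",
                                    "two_colonies", "half_plane_antibiotic",
                                    "three_species", "s2_rule"))
  p <- do.call(default_params,
               c(list(three_species = scenario == "three_species"), params))
  phase <- check_keys(phase, c("support_threshold", "rule", "bbar_min",
                               "bbar_max"), "phase")
  if (is.null(phase$rule) && scenario == "s2_rule") phase$rule <- "b1_plus_b2"
  if (is.null(phase$bbar_min) && (is.null(phase$rule) ||
                                  phase$rule == "b1_only"))
    phase$bbar_min <- p$bbar_min
  if (is.null(phase$bbar_max) && (is.null(phase$rule) ||
                                  phase$rule == "b1_only"))
    phase$bbar_max <- p$bbar_max
  pc <- do.call(phase_config, phase)

  integrator <- check_keys(integrator, c("dt", "scheme", "gs_tol",
                                         "gs_max_iter"), "integrator")
  if (is.null(integrator$dt)) integrator$dt <- p$dt
  ic <- do.call(integrator_config, integrator)

  output <- check_keys(output, c("record_every", "snapshot_times"), "output")
  out <- utils::modifyList(list(record_every = 50L, snapshot_times = NULL),
                           output)
  structure(list(mesh = spec, params = p, phase = pc, integrator = ic,
                 scenario = scenario, horizon = horizon, output = out),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' An empty document (or `{}`) resolves to the full set of defaults.
#' Validation errors name the offending key.
#'
#' @param path path to a JSON configuration file.
#' @return A resolved `run_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- if (!nzchar(trimws(txt))) list()
         else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  allowed <- c("mesh", "params", "phase", "integrator", "scenario",
               "horizon", "output")
  bad <- setdiff(names(doc), allowed)
  if (length(bad))
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "))
  args <- list(mesh = as.list(doc$mesh), params = as.list(doc$params),
               phase = as.list(doc$phase),
               integrator = as.list(doc$integrator),
               output = as.list(doc$output))
  if (!is.null(doc$scenario)) args$scenario <- doc$scenario
  if (!is.null(doc$horizon)) args$horizon <- doc$horizon
  do.call(run_config, args)
}

#' Write a run configuration to JSON
#'
#' [load_config()] of the written file reproduces the configuration
#' (round-trip identity).
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  doc <- list(
    mesh = cfg$mesh[c("nx", "ny", "h", "d_x", "d_y", "seed")],
    params = cfg$params[setdiff(names(cfg$params), "three_species")],
    phase = unclass(cfg$phase),
    integrator = unclass(cfg$integrator),
    scenario = cfg$scenario, horizon = cfg$horizon,
    output = cfg$output[!vapply(cfg$output, is.null, TRUE)])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a configured simulation
#'
#' Builds the mesh, runs the scenario and (optionally) writes all outputs.
#' Fully deterministic for a given configuration.
#'
#' @param cfg a `run_config` (or path to a JSON config).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param verbose print phase switches.
#' @return The `colony_diagnostics` of the run (invisibly when writing).
#' @export
run_simulation <- function(cfg, out_dir = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  mesh <- vrl_mesh(cfg$mesh)
  scn <- make_scenario(cfg$scenario, params = cfg$params,
                       horizon = cfg$horizon, phase_cfg = cfg$phase)
  diag <- run_scenario(scn, mesh, cfg = cfg$integrator,
                       record_every = cfg$output$record_every,
                       snapshot_times = cfg$output$snapshot_times,
                       verbose = verbose)
  if (!is.null(out_dir)) {
    write_outputs(diag, mesh, out_dir, cfg = cfg)
    return(invisible(diag))
  }
  diag
}

#' Write simulation outputs
#'
#' Emits the node/edge CSV tables, the diagnostics time series CSV, one CSV
#' and one legacy-ASCII VTK unstructured-grid file per snapshot, and a JSON
#' manifest carrying the fully resolved configuration (re-running from the
#' manifest reproduces the outputs bit for bit).
#'
#' @param diag a `colony_diagnostics`.
#' @param mesh the mesh of the run.
#' @param dir output directory (created if missing).
#' @param cfg optional `run_config` to embed in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(diag, mesh, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nodes = file.path(dir, "nodes.csv"),
             edges = file.path(dir, "edges.csv"),
             diagnostics = file.path(dir, "diagnostics.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_mesh_csv(mesh, paths["nodes"], paths["edges"])
  utils::write.csv(diag$series, paths["diagnostics"], row.names = FALSE)
  snaps <- Filter(Negate(is.null), diag$snapshots)
  for (s in snaps) {
    tag <- sprintf("snapshot_t%g", s$t)
    fields <- Filter(Negate(is.null),
                     s[c("b1", "b2", "X", "n", "a", "s1", "s2", "sX",
                         "accumulated")])
    utils::write.csv(cbind(data.frame(x = mesh$nodes[, 1],
                                      y = mesh$nodes[, 2]),
                           as.data.frame(fields)),
                     file.path(dir, paste0(tag, ".csv")), row.names = FALSE)
    write_vtk(mesh, fields, file.path(dir, paste0(tag, ".vtk")))
    paths <- c(paths, file.path(dir, paste0(tag, c(".csv", ".vtk"))))
  }
  manifest <- list(
    package = "vortexsim",
    version = as.character(utils::packageVersion("vortexsim")),
    scenario = diag$scenario, horizon = diag$horizon, dt = diag$dt,
    mesh_seed = if (!is.null(mesh$spec)) mesh$spec$seed else NA,
    switches = diag$switches, clipped_mass = diag$clipped,
    config = if (is.null(cfg)) NULL else
      jsonlite::fromJSON(jsonlite::toJSON(list(
        mesh = cfg$mesh[c("nx", "ny", "h", "d_x", "d_y", "seed")],
        params = cfg$params[setdiff(names(cfg$params), "three_species")],
        phase = unclass(cfg$phase), integrator = unclass(cfg$integrator),
        scenario = cfg$scenario, horizon = cfg$horizon),
        auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Export mesh and fields as a legacy VTK unstructured grid
#'
#' Writes the Delaunay triangulation with one `POINT_DATA` scalar array per
#' field, readable by ParaView/VTK and by any plain-text parser.
#'
#' @param mesh a complete `vrl_mesh`.
#' @param fields named list of field vectors.
#' @param path output `.vtk` path.
#' @export
write_vtk <- function(mesh, fields, path) {
  n <- nrow(mesh$nodes)
  tri <- mesh_triangles(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vortexsim VRL snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tri), 4 * nrow(tri)), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L,
                     tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tri)), con)
  writeLines(rep("5", nrow(tri)), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", fields[[nm]]), con)
  }
  invisible(path)
}

# triangles of the natural-neighbor graph (triples of mutually adjacent
# nodes); on a Delaunay graph these are exactly the Delaunay triangles
mesh_triangles <- function(mesh) {
  n <- nrow(mesh$nodes)
  adj <- vector("list", n)
  ed <- mesh$edges
  for (e in seq_len(nrow(ed))) {
    i <- ed$i[e]; j <- ed$j[e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- vector("list", nrow(ed))
  for (e in seq_len(nrow(ed))) {
    i <- ed$i[e]; j <- ed$j[e]
    common <- intersect(adj[[i]], adj[[j]])
    common <- common[common > j & j > i]
    if (length(common))
      out[[e]] <- cbind(i, j, common)
  }
  tri <- do.call(rbind, out)
  if (is.null(tri)) tri <- matrix(integer(0), ncol = 3)
  tri
}

#' Command-line interface
#'
#' Subcommands: `mesh-stats` (print [neighbor_statistics()] as JSON), `run`
#' (run a scenario and write outputs) and `sweep` (sensitivity sweep).
#' Options are `--key value` pairs; see the README.
#'
#' @param args character vector of arguments; defaults to the command line.
#' @return Exit status 0, invisibly.
#' @export
vortexsim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: vortexsim <mesh-stats|run|sweep> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  num <- function(k, d) if (is.null(opt[[k]])) d else as.numeric(opt[[k]])
  chr <- function(k, d) if (is.null(opt[[k]])) d else opt[[k]]
  if (cmd == "mesh-stats") {
    spec <- mesh_spec(nx = num("nx", 100), ny = num("ny", 100),
                      h = num("h", 1),
                      d_x = num("d", 0.5 * num("h", 1)),
                      d_y = num("d", 0.5 * num("h", 1)),
                      seed = num("seed", 1))
    stats <- neighbor_statistics(vrl_mesh(spec), c = num("c", 4))
    stats$offset_counts <- NULL
    cat(jsonlite::toJSON(stats, auto_unbox = TRUE, digits = NA), "\n")
  } else if (cmd == "run") {
    cfg <- if (!is.null(opt$config)) load_config(opt$config) else run_config()
    if (!is.null(opt$scenario))
      cfg <- run_config(mesh = cfg$mesh[c("nx", "ny", "h", "d_x", "d_y",
                                          "seed")],
                        scenario = opt$scenario, horizon = cfg$horizon)
    if (!is.null(opt[["mesh-seed"]]))
      cfg$mesh$seed <- as.integer(num("mesh-seed", 1))
    out <- chr("out-dir", "vortexsim-out")
    run_simulation(cfg, out_dir = out, verbose = TRUE)
    cat("outputs written to ", out, "\n", sep = "")
  } else if (cmd == "sweep") {
    mesh <- vrl_mesh(mesh_spec(nx = num("nx", 64), ny = num("ny", 64),
                               seed = num("seed", 1)))
    res <- run_sweep(mesh, horizon = num("horizon", 20))
    out <- chr("out-dir", ".")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out, "sweep.csv"), row.names = FALSE)
    print(res)
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list()
  k <- 1
  while (k <= length(args)) {
    if (!startsWith(args[k], "--")) stop("expected --option, got ", args[k])
    key <- sub("^--", "", args[k])
    if (k == length(args) || startsWith(args[k + 1], "--"))
      stop("missing value for --", key)
    opt[[key]] <- args[k + 1]
    k <- k + 2
  }
  opt
}
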