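#' Run configuration for the full pipeline
#'
#' A run configuration is a plain named list (or YAML file with the same
#' structure) with any of the stage blocks `generate`, `simulate`, `analyze`,
#' `dissolve`, plus `out_dir` and a global `seed` which fans out to fixed
#' per-stage sub-seeds. Stages run in order; each stage consumes its
#' predecessor's outputs.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Returns findings as data, not errors: blocking problems (`level =
#' "error"`) and advisories (`level = "warning"`, e.g. a Reynolds number
#' above the desk-scale envelope or a lattice Mach number above the low-Mach
#' contract).
#'
#' @param config a configuration list (see [read_run_config()]).
#' @return A tibble with columns `level`, `field`, `message` (zero rows if
#'   clean).
#' @export
validate_config <- function(config) {
  rows <- list()
  note <- function(level, field, message)
    rows[[length(rows) + 1]] <<- tibble(level = level, field = field,
                                        message = message)
  gen <- config$generate
  if (!is.null(gen)) {
    ok <- tryCatch({ do.call(coral_params, gen); TRUE },
                   error = function(e) { note("error", "generate", conditionMessage(e)); FALSE })
  } else if (is.null(config$geometry_file)) {
    note("error", "generate", "no geometry source: give a `generate` block or `geometry_file`")
  } else if (!file.exists(config$geometry_file)) {
    note("error", "geometry_file",
         sprintf("geometry file does not exist: %s", config$geometry_file))
  }
  sim <- config$simulate
  if (!is.null(sim)) {
    spacing <- sim$spacing %||% config$generate$spacing %||% 3.75e-4
    u_in <- sim$u_inlet %||% 8.33e-4
    width <- sim$width %||% 0.012
    nu <- sim$nu %||% 1e-6
    tau <- sim$tau %||% 0.9
    if (tau <= 0.5)
      note("error", "simulate.tau",
           sprintf("tau = %.3f <= 0.5 violates BGK stability", tau))
    else {
      # discretization implied by the requested tau, before any clamping
      dt <- (tau - 0.5) / 3 * spacing^2 / nu
      u_lat <- u_in * dt / spacing
      if (u_lat > 0.1)
        note("warning", "simulate.u_inlet",
             sprintf("u_inlet implies lattice velocity %.3f above the low-Mach contract (0.1); tau will be reduced", u_lat))
      tryCatch(flow_config(u_inlet = u_in, width = width, spacing = spacing,
                           nu = nu, tau = tau),
               error = function(e) note("error", "simulate", conditionMessage(e)))
    }
    re <- reynolds(u_in, width, nu)
    if (re > 150)
      note("warning", "simulate.u_inlet",
           sprintf("Re = %.0f is above the desk-scale envelope (150); expect BGK instability on coarse grids", re))
  }
  dis <- config$dissolve
  if (!is.null(dis)) {
    if (!is.null(dis$pH) && (dis$pH <= 0 || dis$pH >= 14))
      note("error", "dissolve.pH", "pH must lie in (0, 14)")
  }
  if (length(rows)) do.call(rbind, rows)
  else tibble(level = character(), field = character(), message = character())
}

stage_seed <- function(seed, stage)
  (as.integer(seed) * 1009L + match(stage, c("generate", "simulate", "analyze",
                                             "dissolve"))) %% 2147483647L

#' Execute the generate / simulate / analyze / dissolve pipeline
#'
#' Runs the requested stages in order, writing each stage's outputs in its
#' standard formats (TIFF+JSON geometry, VTK field, CSV statistics and
#' traces, CSV dissolution table) under `config$out_dir`, and returns a run
#' manifest recording configuration, convergence flags and per-file MD5
#' checksums. Deterministic stages reproduce bit-identical outputs when
#' re-run with the same configuration and seed.
#'
#' @param config configuration list or YAML path (see [read_run_config()]).
#' @return The manifest (list), invisibly written as `manifest.json` in the
#'   output directory. Stage results are attached under `$results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stopf("configuration errors:\n%s",
          paste(sprintf("- [%s] %s", findings$field[findings$level == "error"],
                        findings$message[findings$level == "error"]),
                collapse = "\n"))
  out_dir <- config$out_dir %||% stopf("config needs `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  files <- character(0)
  manifest <- list(config = config, seed = seed, stages = list())
  results <- list()

  geom <- NULL
  if (!is.null(config$generate)) {
    gen <- config$generate
    gen$seed <- gen$seed %||% stage_seed(seed, "generate")
    geom <- generate_coral(do.call(coral_params, gen))
    gpath <- file.path(out_dir, "geometry.tif")
    write_geometry(geom, gpath)
    files <- c(files, gpath, paste0(gpath, ".json"))
    manifest$stages$generate <- list(done = TRUE, seed = gen$seed)
    results$geometry <- geom
  } else if (!is.null(config$geometry_file)) {
    geom <- read_geometry(config$geometry_file)
    results$geometry <- geom
  }

  field <- NULL
  if (!is.null(config$simulate)) {
    if (is.null(geom)) stopf("simulate stage needs a geometry")
    sim <- config$simulate
    cfg <- flow_config(
      u_inlet = sim$u_inlet %||% 8.33e-4, width = sim$width %||% 0.012,
      spacing = geom$spacing, nu = sim$nu %||% 1e-6, tau = sim$tau %||% 0.9,
      max_steps = sim$max_steps %||% 6000L,
      check_every = sim$check_every %||% 100L, tol = sim$tol %||% 2e-4,
      ramp_steps = sim$ramp_steps %||% 400L)
    field <- run_to_quasi_steady(geom, cfg)
    vpath <- file.path(out_dir, "field.vtk")
    write_field_vtk(field, vpath)
    kpath <- file.path(out_dir, "kinetic_energy.csv")
    write.csv(field$ke_trace, kpath, row.names = FALSE)
    files <- c(files, vpath, kpath)
    manifest$stages$simulate <- list(done = TRUE, steps = field$steps,
                                     converged = field$converged,
                                     re = cfg$re, tau = cfg$tau)
    results$field <- field
  }

  if (!is.null(config$analyze)) {
    if (is.null(field)) stopf("analyze stage needs a simulated field")
    an <- config$analyze
    reg <- coral_regions(geom)
    asym <- asymmetry_differences(field, reg$slice_pairs)
    apath <- file.path(out_dir, "asymmetry.csv")
    write.csv(asym, apath, row.names = FALSE)
    axial <- axial_decomposition(field, reg$axial_sections, reg$channel_mask)
    xpath <- file.path(out_dir, "axial_sections.csv")
    write.csv(axial, xpath, row.names = FALSE)
    files <- c(files, apath, xpath)
    res_list <- NULL
    if (isTRUE(an$residence %||% TRUE)) {
      n <- an$n_particles %||% 200L
      rad <- an$seed_radius %||% 10
      sl_seed <- stage_seed(seed, "analyze")
      res_list <- lapply(names(reg$subvolumes), function(nm) {
        starts <- seed_particles(geom, reg$subvolumes[[nm]], n, rad,
                                 seed = sl_seed)
        sl <- trace_streamlines(field, starts,
                                max_steps = an$max_steps %||% 4000L)
        rt <- residence_time(sl, reg$subvolumes[[nm]])
        tibble(region = nm, t_bar = rt$t_bar, t_bar_raw = rt$t_bar_raw,
               n_streamline = rt$n_streamline)
      })
      res_tbl <- do.call(rbind, res_list)
      rpath <- file.path(out_dir, "residence_times.csv")
      write.csv(res_tbl, rpath, row.names = FALSE)
      files <- c(files, rpath)
      results$residence <- res_tbl
    }
    manifest$stages$analyze <- list(done = TRUE)
    results$asymmetry <- asym
    results$axial <- axial
  }

  if (!is.null(config$dissolve)) {
    dis <- config$dissolve
    pipe <- pipe_model(R_O = dis$R_O %||% 0.006, R_I = dis$R_I %||% 0.0015,
                       H = dis$H %||% 0.04, n0 = dis$n0 %||% 0.1)
    scen <- acid_scenario(scenario = dis$scenario %||% "inside-acid",
                          pH = dis$pH %||% 7.87, Q = dis$Q,
                          t_years = dis$t_years %||% 1,
                          label = dis$label %||% NULL)
    proj <- project_scenario(pipe, scen)
    dpath <- file.path(out_dir, "dissolution.csv")
    write.csv(proj, dpath, row.names = FALSE)
    files <- c(files, dpath)
    manifest$stages$dissolve <- list(done = TRUE)
    results$dissolution <- proj
  }

  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest[c("seed", "stages", "checksums")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$results <- results
  invisible(manifest)
}
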