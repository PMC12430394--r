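# Synthetic fixture generators and the config-driven report runner.
# Gaussian-atom model systems have closed-form descriptor values for a
# single center and are exactly extensive for well-separated copies,
# which makes them the idealized limit of the homologous-series
# benchmarks: descriptor-vs-size trends are exactly linear.

#' Build a line of identical Gaussian atoms
#'
#' Places `n_centers` identical Gaussian model atoms on the z axis and
#' returns the geometry together with the analytic promolecular field.
#' For one center every descriptor has a closed form; for separations
#' large against `1/sqrt(exponent)` descriptors are `n_centers` times
#' the monomer values (extensivity).
#'
#' @param n_centers number of atoms.
#' @param exponent Gaussian exponent (bohr^-2); default 1.
#' @param electrons_per_center norm per atom; default 1.
#' @param separation spacing between neighbors (bohr); default 30.
#' @return list with `geometry`, `field` (`ita_field`) and `refs` (a
#'   matching single-Gaussian reference table keyed by `"H"`).
#' @export
make_gaussian_system <- function(n_centers, exponent = 1,
                                 electrons_per_center = 1,
                                 separation = 30) {
  stopifnot(n_centers >= 1, separation >= 0, exponent > 0)
  coords <- cbind(0, 0, (seq_len(n_centers) - 1) * separation)
  geom <- geometry(rep("H", n_centers), coords,
                   fragment_of = seq_len(n_centers))
  fields <- lapply(seq_len(n_centers), function(i)
    gaussian_field(exponent, electrons_per_center, coords[i, ]))
  refs <- list(H = atom_reference("H", electrons_per_center, exponent,
                                  electrons_per_center))
  list(geometry = geom, field = do.call(field_sum, fields), refs = refs)
}

#' Generate a homologous series of geometries
#'
#' `chain` places single-atom fragments on a line with the given
#' spacing; `ring_cluster` places them on a 2-D square lattice with
#' seeded jitter (a stand-in for compact molecular clusters whose
#' fragment adjacency graph is two-dimensional).
#'
#' @param family `"chain"` or `"ring_cluster"`.
#' @param n_min,n_max fragment-count range (n_max >= n_min >= 1).
#' @param spacing nearest-neighbor spacing (bohr); default 30.
#' @param seed integer seed for the lattice jitter (recorded in the
#'   output for replay); ignored for chains.
#' @return list of `ita_geometry` objects (fragments assigned), one per
#'   n, with attributes `family`, `spacing`, `seed`.
#' @export
make_homologous_series <- function(family = c("chain", "ring_cluster"),
                                   n_min, n_max, spacing = 30, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_max >= n_min, n_min >= 1)
  out <- lapply(n_min:n_max, function(n) {
    if (family == "chain") {
      coords <- cbind(0, 0, (seq_len(n) - 1) * spacing)
    } else {
      side <- ceiling(sqrt(n))
      ix <- (seq_len(n) - 1) %% side
      iy <- (seq_len(n) - 1) %/% side
      jit <- .with_seed(seed + n, matrix(stats::runif(2 * n, -0.15, 0.15),
                                         n, 2)) * spacing
      coords <- cbind(ix * spacing + jit[, 1], iy * spacing + jit[, 2], 0)
    }
    geometry(rep("H", n), coords, fragment_of = seq_len(n))
  })
  attr(out, "family") <- family
  attr(out, "spacing") <- spacing
  attr(out, "seed") <- as.integer(seed)
  out
}

# Run code under a temporary RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parse a flat key/value configuration file
#'
#' TOML-dialect subset: `key = value` lines, `#` comments, quoted or
#' bare scalar values.  Physical quantities carry explicit unit suffixes
#' in their keys (e.g. `separation_bohr`, `zeta_angstrom`).
#'
#' @param path config file path.
#' @return named list; numeric-looking values are converted.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    p <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(p) != 2) stop("config error: cannot parse line '", ln, "'")
    val <- gsub('^"|"$', "", p[2])
    num <- suppressWarnings(as.numeric(val))
    out[[p[1]]] <- if (is.na(num)) val else num
  }
  out
}

#' Run a configured task and write a report bundle
#'
#' Tasks: `compute` (descriptor vector of a Gaussian fixture or an XYZ
#' geometry, written as CSV), `fit` (per-descriptor LR models of a
#' packaged table, written as JSON) and `gebf` (fragmentation plan of a
#' fixture series member, written as JSON).  A log file records package
#' version, grid spec and seeds so descriptor values are auditable.
#'
#' @param config path to a [read_config()] file with at least `task` and
#'   `out_dir`.
#' @return named list of output paths, invisibly.
#' @export
run_report <- function(config) {
  cfg <- read_config(config)
  task <- cfg$task
  if (is.null(task)) stop("config error: missing 'task'")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_radial <- as.integer(cfg$grid_n_radial %||% 75)
  n_angular <- as.integer(cfg$grid_n_angular %||% 288)
  log_lines <- c(sprintf("itacorr %s",
                         as.character(utils::packageVersion("itacorr"))),
                 sprintf("task = %s", task),
                 sprintf("grid = %d radial x %d angular", n_radial,
                         n_angular))
  outputs <- list()
  if (task == "compute") {
    if (!is.null(cfg$geometry_xyz)) {
      if (!file.exists(cfg$geometry_xyz)) {
        stop("config error: no such file: ", cfg$geometry_xyz)
      }
      geom <- read_xyz(cfg$geometry_xyz)
      field <- promolecular_field(geom)
      refs <- load_atom_references()
    } else {
      sys <- make_gaussian_system(
        n_centers = as.integer(cfg$n_centers %||% 1),
        exponent = cfg$exponent_invbohr2 %||% 1,
        electrons_per_center = cfg$electrons_per_center %||% 1,
        separation = cfg$separation_bohr %||% 30)
      geom <- sys$geometry; field <- sys$field; refs <- sys$refs
    }
    grid <- build_grid(geom, n_radial, n_angular)
    vec <- compute_all(geom, field, refs, grid)
    out <- file.path(out_dir, "descriptors.csv")
    utils::write.csv(data.frame(descriptor = names(vec),
                                value_au = as.numeric(vec)),
                     out, row.names = FALSE)
    outputs$descriptors <- out
    log_lines <- c(log_lines, sprintf("n_atoms = %d", n_atoms(geom)))
  } else if (task == "fit") {
    if (is.null(cfg$table)) stop("config error: missing 'table'")
    tab <- read_ita_table(cfg$table)
    fits <- fit_all(tab)
    out <- file.path(out_dir, "models.json")
    jsonlite::write_json(
      lapply(fits$models, function(m)
        m[c("descriptor", "slope", "intercept", "n_points", "r_squared",
            "rmsd")]),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs$models <- out
    log_lines <- c(log_lines, sprintf("table = %s", cfg$table))
  } else if (task == "gebf") {
    seed <- as.integer(cfg$seed %||% 1)
    series <- make_homologous_series(
      family = cfg$family %||% "ring_cluster",
      n_min = as.integer(cfg$n_fragments %||% 6),
      n_max = as.integer(cfg$n_fragments %||% 6),
      spacing = cfg$spacing_bohr %||% 6, seed = seed)
    plan <- build_plan(series[[1]],
                       zeta = cfg$zeta_angstrom %||% 4.0,
                       gamma_max = as.integer(cfg$gamma_max %||% 6))
    out <- file.path(out_dir, "plan.json")
    write_plan(plan, out)
    outputs$plan <- out
    log_lines <- c(log_lines, sprintf("seed = %d", seed))
  } else {
    stop("config error: unknown task '", task, "'")
  }
  log_path <- file.path(out_dir, "report.log")
  writeLines(log_lines, log_path)
  outputs$log <- log_path
  invisible(outputs)
}
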