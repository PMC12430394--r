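# Generalized energy-based fragmentation (GEBF): primitive/derivative
# subsystem construction with inclusion-exclusion coefficients, total
# energy assembly with the point-charge double-counting correction, and
# the combination with LR(ITA) correlation-energy models.
#
# Subsystem coefficients are obtained from the closure of the primitive
# set family under intersection: processing distinct intersections in
# decreasing size with C(S) = 1 - sum of C(T) over strict supersets T
# yields sum_{m: f in S_m} C_m = 1 for every fragment f (and for every
# covered fragment pair), the single-counting identity behind Eq.-style
# energy assembly.

#' Build a GEBF fragmentation plan
#'
#' Primitive subsystems are grown around each fragment from all
#' fragments whose minimal interatomic distance is at most `zeta`,
#' truncated to the `gamma_max` nearest (ties broken by lower fragment
#' index); primitives that are subsets of another retained primitive are
#' dropped.  Derivative subsystems with signed integer coefficients are
#' generated by inclusion-exclusion over primitive intersections.
#'
#' @param geom an `ita_geometry` with fragments assigned (see
#'   [detect_fragments()]).
#' @param zeta distance threshold in Angstrom (converted to bohr
#'   internally); default 4.0.
#' @param gamma_max maximum number of fragments per subsystem; default 6.
#' @return object of class `ita_plan`: list with `fragments` (list of
#'   atom-index vectors), `subsystems` (list of fragment-index vectors),
#'   `coefficients` (integers), `kind` (`"primitive"`/`"derivative"`)
#'   and `parameters`.
#' @export
build_plan <- function(geom, zeta = 4.0, gamma_max = 6L) {
  if (is.null(geom$fragment_of)) {
    stop("geometry has no fragment assignment; run detect_fragments() first")
  }
  stopifnot(zeta > 0, gamma_max >= 1)
  zeta_bohr <- zeta * BOHR_PER_ANGSTROM
  nfrag <- max(geom$fragment_of)
  fragments <- split(seq_len(n_atoms(geom)), geom$fragment_of)
  # minimal interatomic distance between fragments
  d <- as.matrix(stats::dist(geom$coords))
  fd <- matrix(0, nfrag, nfrag)
  for (i in seq_len(nfrag)) {
    for (j in seq_len(nfrag)) {
      if (j <= i) next
      fd[i, j] <- fd[j, i] <- min(d[fragments[[i]], fragments[[j]]])
    }
  }
  primitives <- lapply(seq_len(nfrag), function(f) {
    nb <- which(fd[f, ] <= zeta_bohr)     # includes f itself (distance 0)
    if (length(nb) > gamma_max) {
      if (gamma_max == 1L) {
        nb <- f
      } else {
        others <- setdiff(nb, f)
        others <- others[order(fd[f, others], others)]
        nb <- sort(c(f, others[seq_len(gamma_max - 1L)]))
      }
      warning("primitive subsystem of fragment ", f,
              " truncated to the ", gamma_max, " nearest fragments")
    }
    sort(nb)
  })
  # drop primitives contained in another retained primitive (duplicates
  # count as contained); larger sets are retained first
  prims <- list()
  for (i in order(lengths(primitives), decreasing = TRUE)) {
    contained <- any(vapply(prims, function(s)
      all(primitives[[i]] %in% s), logical(1)))
    if (!contained) prims[[length(prims) + 1L]] <- primitives[[i]]
  }

  # closure under intersection
  closure <- prims
  closure_keys <- vapply(closure, paste, character(1), collapse = ",")
  frontier <- closure
  while (length(frontier) > 0) {
    fresh <- list()
    for (s in frontier) {
      for (p in prims) {
        it <- intersect(s, p)
        if (length(it) == 0) next
        k <- paste(sort(it), collapse = ",")
        if (!k %in% closure_keys) {
          it <- sort(it)
          fresh[[length(fresh) + 1L]] <- it
          closure[[length(closure) + 1L]] <- it
          closure_keys <- c(closure_keys, k)
        }
      }
    }
    frontier <- fresh
  }
  # deterministic ordering: decreasing size, then lexicographic indices
  ord <- order(-lengths(closure),
               vapply(closure, function(s)
                 paste(sprintf("%06d", s), collapse = ","), character(1)))
  closure <- closure[ord]
  coef <- integer(length(closure))
  for (i in seq_along(closure)) {
    base <- 1L
    for (j in seq_len(i - 1L)) {
      if (length(closure[[j]]) > length(closure[[i]]) &&
            all(closure[[i]] %in% closure[[j]])) {
        base <- base - coef[j]
      }
    }
    coef[i] <- base
  }
  prim_keys <- vapply(prims, function(s) paste(sort(s), collapse = ","),
                      character(1))
  kind <- ifelse(vapply(closure, paste, character(1), collapse = ",") %in%
                   prim_keys, "primitive", "derivative")
  nonzero <- coef != 0L
  structure(
    list(fragments = fragments,
         subsystems = closure[nonzero],
         coefficients = coef[nonzero],
         kind = kind[nonzero],
         parameters = list(zeta = zeta, gamma_max = as.integer(gamma_max))),
    class = "ita_plan"
  )
}

#' @export
print.ita_plan <- function(x, ...) {
  cat(sprintf(
    "<ita_plan: %d fragments, %d subsystems (%d primitive, %d derivative), zeta = %g A, gamma_max = %d>\n",
    length(x$fragments), length(x$subsystems), sum(x$kind == "primitive"),
    sum(x$kind == "derivative"), x$parameters$zeta, x$parameters$gamma_max))
  invisible(x)
}

#' Assemble a total energy from subsystem energies
#'
#' `E_tot = sum_m C_m E_m - (sum_m C_m - 1) sum_{A<B} Q_A Q_B / R_AB`:
#' the linear combination of embedded-subsystem energies minus the
#' point-charge interaction counted `sum C_m - 1` extra times.
#'
#' @param plan an `ita_plan`.
#' @param energies numeric vector of subsystem energies (hartree),
#'   aligned with `plan$subsystems`.
#' @param geom the full-system `ita_geometry` (for interatomic
#'   distances).
#' @param charges atomic point charges `Q_A` (a.u.), one per atom;
#'   default all zero.
#' @return total energy (hartree).
#' @export
assemble_energy <- function(plan, energies, geom,
                            charges = rep(0, n_atoms(geom))) {
  if (length(energies) != length(plan$subsystems)) {
    stop("need one energy per subsystem (", length(plan$subsystems),
         "), got ", length(energies))
  }
  if (length(charges) != n_atoms(geom)) {
    stop("need one charge per atom")
  }
  csum <- sum(plan$coefficients)
  e <- sum(plan$coefficients * energies)
  if (csum != 1 && any(charges != 0)) {
    d <- as.matrix(stats::dist(geom$coords))
    qq <- outer(charges, charges)
    coulomb <- sum(qq[upper.tri(qq)] / d[upper.tri(d)])
    e <- e - (csum - 1) * coulomb
  }
  e
}

#' GEBF combination of LR(ITA) correlation energies
#'
#' Total correlation energy `sum_m C_m (slope * x_m + intercept)` from
#' per-subsystem descriptor values and a fitted [fit_lr()] model.  No
#' point-charge term enters: the classical charge correction carries no
#' correlation component.
#'
#' @param plan an `ita_plan`.
#' @param subsystem_ita descriptor value per subsystem (a.u.), aligned
#'   with `plan$subsystems`.
#' @param model an `ita_lr` model.
#' @return total correlation energy (hartree).
#' @export
gebf_lr_correlation <- function(plan, subsystem_ita, model) {
  if (length(subsystem_ita) != length(plan$subsystems)) {
    stop("need one descriptor value per subsystem")
  }
  sum(plan$coefficients * predict(model, subsystem_ita))
}

#' Serialize a fragmentation plan to JSON
#'
#' @param plan an `ita_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(parameters = plan$parameters,
         fragments = plan$fragments,
         subsystems = plan$subsystems,
         coefficients = plan$coefficients,
         kind = plan$kind),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fragmentation plan from JSON
#'
#' @param path path written by [write_plan()].
#' @return an `ita_plan`.
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(fragments = lapply(x$fragments, as.integer),
         subsystems = lapply(x$subsystems, as.integer),
         coefficients = as.integer(x$coefficients),
         kind = x$kind,
         parameters = list(zeta = x$parameters$zeta,
                           gamma_max = as.integer(x$parameters$gamma_max))),
    class = "ita_plan"
  )
}
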