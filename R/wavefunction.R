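# Wavefunction-backed density fields: contracted Gaussian basis sets with
# real spherical-harmonic angular parts (s, p, d, f), molecular-orbital
# coefficients and occupations, plus Molden-format I/O.
#
# Convention: contraction coefficients multiply unit-normalized primitive
# spherical Gaussians
#   phi_k = N(a_k, l) p_lm(r - R) exp(-a_k |r - R|^2),
# where p_lm is the real solid harmonic r^l Ybar_lm (sphere-normalized)
# and N(a, l) = sqrt(2 (2a)^(l + 3/2) / Gamma(l + 3/2)).  Contracted
# functions are used as-is (no extra renormalization); the packaged
# writer and reader round-trip this convention exactly.

.l_letters <- c(s = 0L, p = 1L, d = 2L, f = 3L)

# Real solid harmonics p_lm(x, y, z) and gradients, in Molden component
# order (s; p: x, y, z; d, f: m = 0, +1, -1, +2, -2 [, +3, -3]).
# Each entry: function(x, y, z) -> list(v, dx, dy, dz).
.solid_harmonics <- local({
  h <- list()
  c00 <- 0.5 / sqrt(pi)
  h[["0"]] <- list(function(x, y, z) {
    o <- rep(c00, length(x)); z0 <- numeric(length(x))
    list(v = o, dx = z0, dy = z0, dz = z0)
  })
  c1 <- sqrt(3 / (4 * pi))
  h[["1"]] <- list(
    function(x, y, z) list(v = c1 * x, dx = rep(c1, length(x)),
                           dy = numeric(length(x)), dz = numeric(length(x))),
    function(x, y, z) list(v = c1 * y, dx = numeric(length(x)),
                           dy = rep(c1, length(x)), dz = numeric(length(x))),
    function(x, y, z) list(v = c1 * z, dx = numeric(length(x)),
                           dy = numeric(length(x)), dz = rep(c1, length(x)))
  )
  c20 <- sqrt(5 / (16 * pi)); c21 <- sqrt(15 / (4 * pi))
  c22 <- sqrt(15 / (16 * pi))
  h[["2"]] <- list(
    function(x, y, z) list(v = c20 * (2 * z^2 - x^2 - y^2),
                           dx = -2 * c20 * x, dy = -2 * c20 * y,
                           dz = 4 * c20 * z),
    function(x, y, z) list(v = c21 * x * z, dx = c21 * z,
                           dy = numeric(length(x)), dz = c21 * x),
    function(x, y, z) list(v = c21 * y * z, dx = numeric(length(x)),
                           dy = c21 * z, dz = c21 * y),
    function(x, y, z) list(v = c22 * (x^2 - y^2), dx = 2 * c22 * x,
                           dy = -2 * c22 * y, dz = numeric(length(x))),
    function(x, y, z) list(v = c21 * x * y, dx = c21 * y, dy = c21 * x,
                           dz = numeric(length(x)))
  )
  c30 <- sqrt(7 / (16 * pi)); c31 <- sqrt(21 / (32 * pi))
  c32 <- sqrt(105 / (16 * pi)); c32m <- sqrt(105 / (4 * pi))
  c33 <- sqrt(35 / (32 * pi))
  h[["3"]] <- list(
    function(x, y, z) list(v = c30 * z * (2 * z^2 - 3 * x^2 - 3 * y^2),
                           dx = -6 * c30 * x * z, dy = -6 * c30 * y * z,
                           dz = c30 * (6 * z^2 - 3 * x^2 - 3 * y^2)),
    function(x, y, z) list(v = c31 * x * (4 * z^2 - x^2 - y^2),
                           dx = c31 * (4 * z^2 - 3 * x^2 - y^2),
                           dy = -2 * c31 * x * y, dz = 8 * c31 * x * z),
    function(x, y, z) list(v = c31 * y * (4 * z^2 - x^2 - y^2),
                           dx = -2 * c31 * x * y,
                           dy = c31 * (4 * z^2 - x^2 - 3 * y^2),
                           dz = 8 * c31 * y * z),
    function(x, y, z) list(v = c32 * z * (x^2 - y^2), dx = 2 * c32 * x * z,
                           dy = -2 * c32 * y * z, dz = c32 * (x^2 - y^2)),
    function(x, y, z) list(v = c32m * x * y * z, dx = c32m * y * z,
                           dy = c32m * x * z, dz = c32m * x * y),
    function(x, y, z) list(v = c33 * x * (x^2 - 3 * y^2),
                           dx = 3 * c33 * (x^2 - y^2), dy = -6 * c33 * x * y,
                           dz = numeric(length(x))),
    function(x, y, z) list(v = c33 * y * (3 * x^2 - y^2),
                           dx = 6 * c33 * x * y, dy = 3 * c33 * (x^2 - y^2),
                           dz = numeric(length(x)))
  )
  h
})

# Norm of a primitive spherical Gaussian of angular momentum l.
.primitive_norm <- function(alpha, l) {
  sqrt(2 * (2 * alpha)^(l + 1.5) / gamma(l + 1.5))
}

#' Construct a wavefunction record
#'
#' @param shells list of shells, each a list with fields `center`
#'   (atom index), `l` (0-3), `exponents` and `coefficients` (equal
#'   length).  Spherical-harmonic angular functions only; each shell
#'   contributes `2l + 1` basis functions in Molden component order.
#' @param mo_coefficients numeric matrix, one row per basis function, one
#'   column per molecular orbital.
#' @param occupations electron occupation per orbital (>= 0).
#' @param spherical logical; Cartesian d/f basis sets are not supported
#'   and must be flagged `FALSE` by readers so construction fails loudly.
#' @return an object of class `ita_wavefunction`.
#' @export
wavefunction_record <- function(shells, mo_coefficients, occupations,
                                spherical = TRUE) {
  if (!spherical) {
    stop("Cartesian d/f shells are unsupported; ",
         "only spherical-harmonic basis sets are accepted")
  }
  for (sh in shells) {
    stopifnot(length(sh$exponents) == length(sh$coefficients),
              sh$l %in% 0:3, all(sh$exponents > 0))
  }
  nbasis <- sum(vapply(shells, function(sh) 2L * sh$l + 1L, integer(1)))
  mo_coefficients <- as.matrix(mo_coefficients)
  if (nrow(mo_coefficients) != nbasis) {
    stop("MO coefficient rows (", nrow(mo_coefficients),
         ") inconsistent with basis dimension (", nbasis, ")")
  }
  if (length(occupations) != ncol(mo_coefficients)) {
    stop("one occupation per molecular orbital required")
  }
  if (any(occupations < 0)) stop("occupations must be >= 0")
  structure(
    list(shells = shells, mo_coefficients = mo_coefficients,
         occupations = as.numeric(occupations), spherical = TRUE),
    class = "ita_wavefunction"
  )
}

#' @export
print.ita_wavefunction <- function(x, ...) {
  cat(sprintf("<ita_wavefunction: %d shells, %d basis functions, %d MOs>\n",
              length(x$shells), nrow(x$mo_coefficients),
              ncol(x$mo_coefficients)))
  invisible(x)
}

# Evaluate all basis functions: value, gradient and Laplacian matrices
# (n_points x n_basis each).
.eval_basis <- function(wfn, geom, points) {
  points <- .as_points(points)
  n <- nrow(points)
  nbasis <- nrow(wfn$mo_coefficients)
  V <- matrix(0, n, nbasis); Gx <- matrix(0, n, nbasis)
  Gy <- matrix(0, n, nbasis); Gz <- matrix(0, n, nbasis)
  L <- matrix(0, n, nbasis)
  col <- 0L
  for (sh in wfn$shells) {
    ctr <- geom$coords[sh$center, ]
    x <- points[, 1] - ctr[1]; y <- points[, 2] - ctr[2]
    z <- points[, 3] - ctr[3]
    r2 <- x * x + y * y + z * z
    harms <- .solid_harmonics[[as.character(sh$l)]]
    for (m in seq_along(harms)) {
      p <- harms[[m]](x, y, z)
      col <- col + 1L
      for (k in seq_along(sh$exponents)) {
        a <- sh$exponents[k]
        cN <- sh$coefficients[k] * .primitive_norm(a, sh$l)
        e <- cN * exp(-a * r2)
        V[, col] <- V[, col] + e * p$v
        Gx[, col] <- Gx[, col] + e * (p$dx - 2 * a * x * p$v)
        Gy[, col] <- Gy[, col] + e * (p$dy - 2 * a * y * p$v)
        Gz[, col] <- Gz[, col] + e * (p$dz - 2 * a * z * p$v)
        # solid harmonics: Laplacian(p) = 0 and r.grad(p) = l p
        L[, col] <- L[, col] +
          e * p$v * (4 * a^2 * r2 - 2 * a * (2 * sh$l + 3))
      }
    }
  }
  list(V = V, Gx = Gx, Gy = Gy, Gz = Gz, L = L)
}

#' Density field from a wavefunction
#'
#' Builds the total density `rho = sum_i occ_i |phi_i|^2`, its analytic
#' gradient and Laplacian, and the positive-definite kinetic-energy
#' density `t(r) = sum_i occ_i |grad phi_i|^2 / 2` (equivalently
#' `sum_i |grad rho_i|^2 / (8 rho_i)` minus `lap(rho)/8` when the
#' Laplacian form is requested by the Ghosh-Berkowitz-Parr integrand).
#'
#' @param wfn an `ita_wavefunction`.
#' @param geom the matching `ita_geometry` (bohr).
#' @return an orbital-backed `ita_field`.
#' @export
wavefunction_field <- function(wfn, geom) {
  occ <- wfn$occupations
  if (sum(occ) <= 0) stop("empty density: all orbital occupations are zero")
  C <- wfn$mo_coefficients[, occ > 0, drop = FALSE]
  occ <- occ[occ > 0]
  evaluate <- function(points) {
    b <- .eval_basis(wfn, geom, points)
    phi <- b$V %*% C
    gx <- b$Gx %*% C; gy <- b$Gy %*% C; gz <- b$Gz %*% C
    lap_phi <- b$L %*% C
    occm <- rep(occ, each = nrow(phi))
    list(
      rho = rowSums(occm * phi^2),
      grad = cbind(rowSums(2 * occm * phi * gx),
                   rowSums(2 * occm * phi * gy),
                   rowSums(2 * occm * phi * gz)),
      lap = rowSums(2 * occm * (gx^2 + gy^2 + gz^2 + phi * lap_phi)),
      tau = rowSums(occm * (gx^2 + gy^2 + gz^2)) / 2
    )
  }
  density_field(
    n_electrons = sum(occ),
    rho = function(points) evaluate(points)$rho,
    grad = function(points) evaluate(points)$grad,
    lap = function(points) evaluate(points)$lap,
    kinetic_density = function(points) evaluate(points)$tau,
    orbitals = list(occupations = occ, evaluate = evaluate)
  )
}

# ---------------------------------------------------------------- Molden

#' Write geometry and wavefunction to a Molden file
#'
#' Emits `[Atoms] AU`, `[GTO]`, the `[5D]`/`[7F]` spherical flags and
#' `[MO]`, in the package convention documented on
#' [wavefunction_record()].
#'
#' @param geom an `ita_geometry`.
#' @param wfn an `ita_wavefunction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molden <- function(geom, wfn, path) {
  z <- element_data(geom$elements)$number
  out <- c("[Molden Format]", "[Atoms] AU",
           sprintf("%-3s %4d %4d %20.12e %20.12e %20.12e",
                   geom$elements, seq_len(n_atoms(geom)), z,
                   geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]),
           "[GTO]")
  for (a in seq_len(n_atoms(geom))) {
    out <- c(out, sprintf("%4d 0", a))
    for (sh in wfn$shells) {
      if (sh$center != a) next
      out <- c(out,
               sprintf(" %s %4d 1.00", names(.l_letters)[sh$l + 1L],
                       length(sh$exponents)),
               sprintf("  %20.12e %20.12e", sh$exponents, sh$coefficients))
    }
    out <- c(out, "")
  }
  out <- c(out, "[5D]", "[7F]", "[MO]")
  for (i in seq_along(wfn$occupations)) {
    out <- c(out,
             " Sym= A", sprintf(" Ene= %.6f", 0),
             " Spin= Alpha",
             sprintf(" Occup= %.10f", wfn$occupations[i]),
             sprintf(" %4d %20.12e", seq_len(nrow(wfn$mo_coefficients)),
                     wfn$mo_coefficients[, i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a Molden file
#'
#' Parses the `[Atoms]`, `[GTO]` and `[MO]` sections.  The `AU`/`Angs`
#' unit tag is honored; `[5D]`/`[7F]` flags mark the basis as spherical.
#' Files with d or f shells but no spherical flag are rejected (Cartesian
#' high-angular-momentum shells are unsupported).
#'
#' @param path path to the Molden file.
#' @return `list(geometry = <ita_geometry>, wavefunction =
#'   <ita_wavefunction>)`.
#' @export
read_molden <- function(path) {
  lines <- readLines(path)
  tag <- tolower(trimws(lines))
  section_at <- function(name) grep(paste0("^\\[", name, "\\]"), tag)
  for (required in c("atoms", "gto", "mo")) {
    if (length(section_at(required)) == 0) {
      stop("Molden parse error: missing [", required, "] section")
    }
  }
  starts <- grep("^\\[", tag)
  section_end <- function(i) {
    nxt <- starts[starts > i]
    if (length(nxt) == 0) length(lines) else nxt[1] - 1L
  }

  # [Atoms]
  i <- section_at("atoms")[1]
  angs <- grepl("angs", tag[i])
  atom_lines <- lines[seq(i + 1L, section_end(i))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  tok <- strsplit(trimws(atom_lines), "\\s+")
  elements <- vapply(tok, `[[`, character(1), 1)
  coords <- t(vapply(tok, function(t) as.numeric(t[4:6]), numeric(3)))
  if (anyNA(coords)) stop("Molden parse error: bad [Atoms] coordinate line")
  if (angs) coords <- coords * BOHR_PER_ANGSTROM

  # [GTO]
  i <- section_at("gto")[1]
  gto_lines <- lines[seq(i + 1L, section_end(i))]
  shells <- list()
  j <- 1L
  current_atom <- NA_integer_
  while (j <= length(gto_lines)) {
    ln <- trimws(gto_lines[j])
    if (!nzchar(ln)) { current_atom <- NA_integer_; j <- j + 1L; next }
    t <- strsplit(ln, "\\s+")[[1]]
    if (is.na(current_atom)) {
      current_atom <- as.integer(t[1])
      if (is.na(current_atom)) {
        stop("Molden parse error: expected atom index in [GTO], got '",
             ln, "'")
      }
      j <- j + 1L
      next
    }
    letter <- tolower(t[1])
    if (!letter %in% names(.l_letters)) {
      stop("Molden parse error: unknown angular momentum letter '",
           t[1], "'")
    }
    nprim <- as.integer(t[2])
    if (is.na(nprim) || j + nprim > length(gto_lines)) {
      stop("Molden parse error: truncated [GTO] shell")
    }
    prim <- t(vapply(strsplit(trimws(gto_lines[j + seq_len(nprim)]),
                              "\\s+"),
                     function(t) as.numeric(gsub("[dD]", "e", t[1:2])),
                     numeric(2)))
    shells[[length(shells) + 1L]] <-
      list(center = current_atom, l = .l_letters[[letter]],
           exponents = prim[, 1], coefficients = prim[, 2])
    j <- j + 1L + nprim
  }
  max_l <- max(vapply(shells, `[[`, integer(1), "l"))
  spherical_d <- length(section_at("5d")) > 0 ||
    length(section_at("5d7f")) > 0
  spherical_f <- length(section_at("7f")) > 0 ||
    length(section_at("5d7f")) > 0
  if ((max_l >= 2L && !spherical_d) || (max_l >= 3L && !spherical_f)) {
    stop("Cartesian d/f shells are unsupported; ",
         "only spherical-harmonic basis sets ([5D]/[7F]) are accepted")
  }
  nbasis <- sum(vapply(shells, function(sh) 2L * sh$l + 1L, integer(1)))

  # [MO]
  i <- section_at("mo")[1]
  mo_lines <- lines[seq(i + 1L, section_end(i))]
  occupations <- numeric(0)
  coef_cols <- list()
  current <- NULL
  flush <- function() {
    if (is.null(current)) return()
    if (length(current$coef) != nbasis) {
      stop("Molden parse error: truncated [MO] block (",
           length(current$coef), " coefficients, basis dimension ",
           nbasis, ")")
    }
    occupations <<- c(occupations, current$occ)
    coef_cols[[length(coef_cols) + 1L]] <<- current$coef
  }
  for (ln in mo_lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^(sym|ene|spin)\\s*=", tolower(ln))) {
      if (grepl("^sym", tolower(ln))) { flush(); current <- list(occ = 0, coef = numeric(0)) }
      next
    }
    if (grepl("^occup\\s*=", tolower(ln))) {
      if (is.null(current)) current <- list(occ = 0, coef = numeric(0))
      current$occ <- as.numeric(sub("^[^=]*=\\s*", "", ln))
      next
    }
    t <- strsplit(ln, "\\s+")[[1]]
    if (length(t) != 2L || is.na(suppressWarnings(as.integer(t[1])))) {
      stop("Molden parse error: bad [MO] coefficient line '", ln, "'")
    }
    if (is.null(current)) current <- list(occ = 0, coef = numeric(0))
    current$coef[as.integer(t[1])] <- as.numeric(t[2])
  }
  flush()
  if (length(coef_cols) == 0) stop("Molden parse error: empty [MO] section")

  geom <- geometry(elements, coords)
  wfn <- wavefunction_record(shells, do.call(cbind, coef_cols), occupations)
  list(geometry = geom, wavefunction = wfn)
}
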