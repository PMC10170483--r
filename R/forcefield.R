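# Force-field containers and potential functions.
#
# Unit conventions:
#   * pair sigma values are stored in Angstrom (the convention of printed
#     CG parameter tables); epsilon in kJ/mol.
#   * bonded parameters are stored in internal units: k_b in kJ/mol/nm^2,
#     b_eq in nm, k_theta in kJ/mol/rad^2, theta_eq in degrees.
#   * all distance arguments to energy/force functions are in nm.

LJ96_PREFACTOR  <- 27 / 4        # well depth normalised to epsilon
LJ124_PREFACTOR <- 3 * sqrt(3) / 2
KB_KJ           <- 0.0083144621  # Boltzmann constant, kJ/mol/K
KCAL            <- 4.184         # kJ per kcal

#' Lennard-Jones pair parameters
#'
#' Container for a nonbonded pair interaction. Two functional forms are
#' supported: the 9-6 form used between ordinary coarse-grained beads and
#' the softer 12-4 form used for any pair involving the water bead `W`.
#' Both are normalised so that the well depth equals `epsilon` exactly.
#'
#' @param sigma Zero-crossing distance in Angstrom (`sigma > 0`).
#' @param epsilon Well depth in kJ/mol (`epsilon >= 0`).
#' @param form `"lj9-6"` or `"lj12-4"`.
#' @param origin Provenance tag: `"fitted"`, `"similarity"`,
#'   `"combination-rule"`, `"repulsive"` or `"reference"`.
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(sigma, epsilon, form = c("lj9-6", "lj12-4"),
                        origin = "fitted") {
  form <- match.arg(form)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  structure(list(sigma = sigma, epsilon = epsilon, form = form,
                 origin = origin),
            class = "pair_params")
}

#' @export
print.pair_params <- function(x, ...) {
  cat(sprintf("<pair %s  epsilon = %.4f kJ/mol  sigma = %.3f A  [%s]>\n",
              x$form, x$epsilon, x$sigma, x$origin))
  invisible(x)
}

#' Harmonic bond parameters
#'
#' @param k_b Force constant in kJ/mol/nm^2 (energy `U = k_b (b - b_eq)^2`,
#'   no 1/2 prefactor, the LAMMPS `bond_style harmonic` convention).
#' @param b_eq Equilibrium length in nm.
#' @return An object of class `bond_params`.
#' @export
bond_params <- function(k_b, b_eq) {
  stopifnot(k_b > 0, b_eq > 0)
  structure(list(k_b = k_b, b_eq = b_eq), class = "bond_params")
}

#' Harmonic angle parameters
#'
#' @param k_theta Force constant in kJ/mol/rad^2 (energy
#'   `U = k_theta (theta - theta_eq)^2`, no 1/2 prefactor).
#' @param theta_eq Equilibrium angle in degrees, in (0, 180].
#' @param correction_13 Logical; request a repulsive 1-3 LJ correction that
#'   guards against angle collapse when `k_theta` is small. Default `FALSE`.
#' @return An object of class `angle_params`.
#' @export
angle_params <- function(k_theta, theta_eq, correction_13 = FALSE) {
  stopifnot(k_theta > 0, theta_eq > 0, theta_eq <= 180)
  structure(list(k_theta = k_theta, theta_eq = theta_eq,
                 correction_13 = isTRUE(correction_13)),
            class = "angle_params")
}

#' Lennard-Jones 9-6 pair energy and force
#'
#' `U(r) = (27/4) epsilon ((sigma/r)^9 - (sigma/r)^6)`. The minimum sits at
#' `r = (3/2)^(1/3) sigma` with `U = -epsilon`.
#'
#' @param r Distance(s) in nm, `r > 0`.
#' @param p A [pair_params] object (sigma in Angstrom).
#' @param cutoff Optional truncation distance in nm; beyond it the energy
#'   and force are exactly zero (plain truncation).
#' @return Energy in kJ/mol (`lj96_energy`) or the radial force
#'   `-dU/dr` in kJ/mol/nm (`lj96_force`); positive force is repulsive.
#' @export
lj96_energy <- function(r, p, cutoff = Inf) {
  stopifnot(all(r > 0))
  s <- (p$sigma / 10) / r
  u <- LJ96_PREFACTOR * p$epsilon * (s^9 - s^6)
  u[r > cutoff] <- 0
  u
}

#' @rdname lj96_energy
#' @export
lj96_force <- function(r, p, cutoff = Inf) {
  stopifnot(all(r > 0))
  s <- (p$sigma / 10) / r
  f <- LJ96_PREFACTOR * p$epsilon * (9 * s^9 - 6 * s^6) / r
  f[r > cutoff] <- 0
  f
}

#' Lennard-Jones 12-4 pair energy and force
#'
#' `U(r) = (3 sqrt(3)/2) epsilon ((sigma/r)^12 - (sigma/r)^4)`, the form used
#' for any pair involving the coarse-grained water bead. The minimum sits at
#' `r = 3^(1/8) sigma` with `U = -epsilon`.
#'
#' @inheritParams lj96_energy
#' @return Energy in kJ/mol or radial force `-dU/dr` in kJ/mol/nm.
#' @export
lj124_energy <- function(r, p, cutoff = Inf) {
  stopifnot(all(r > 0))
  s <- (p$sigma / 10) / r
  u <- LJ124_PREFACTOR * p$epsilon * (s^12 - s^4)
  u[r > cutoff] <- 0
  u
}

#' @rdname lj124_energy
#' @export
lj124_force <- function(r, p, cutoff = Inf) {
  stopifnot(all(r > 0))
  s <- (p$sigma / 10) / r
  f <- LJ124_PREFACTOR * p$epsilon * (12 * s^12 - 4 * s^4) / r
  f[r > cutoff] <- 0
  f
}

#' Dispatch on the functional form of a pair
#'
#' @inheritParams lj96_energy
#' @return Energy (or force) using the form recorded in `p$form`.
#' @export
lj_energy <- function(r, p, cutoff = Inf) {
  if (p$form == "lj12-4") lj124_energy(r, p, cutoff) else lj96_energy(r, p, cutoff)
}

#' @rdname lj_energy
#' @export
lj_force <- function(r, p, cutoff = Inf) {
  if (p$form == "lj12-4") lj124_force(r, p, cutoff) else lj96_force(r, p, cutoff)
}

#' Harmonic bond energy
#'
#' `U(b) = k_b (b - b_eq)^2` (no 1/2 prefactor).
#'
#' @param b Bond length(s) in nm.
#' @param p A [bond_params] object.
#' @return Energy in kJ/mol.
#' @export
harmonic_bond <- function(b, p) {
  p$k_b * (b - p$b_eq)^2
}

#' Harmonic angle energy
#'
#' `U(theta) = k_theta (theta - theta_eq)^2` with the deviation taken in
#' radians (no 1/2 prefactor).
#'
#' @param theta Angle(s) in degrees.
#' @param p An [angle_params] object.
#' @return Energy in kJ/mol.
#' @export
harmonic_angle <- function(theta, p) {
  d <- (theta - p$theta_eq) * pi / 180
  p$k_theta * d^2
}

#' Lorentz-Berthelot combination rule
#'
#' Cross parameters from the diagonal (self) parameters of two bead types:
#' arithmetic mean for sigma, geometric mean for epsilon. Used as the
#' educated first guess for unparameterized pairs.
#'
#' @param bead_i,bead_j Bead type labels present in `ff`.
#' @param ff A [forcefield] object supplying the diagonal entries.
#' @return A [pair_params] with `origin = "combination-rule"`; the form is
#'   12-4 if either bead is `W`, else 9-6.
#' @export
lorentz_berthelot <- function(bead_i, bead_j, ff) {
  pi_ <- ff_pair_entry(ff, bead_i, bead_i)
  pj  <- ff_pair_entry(ff, bead_j, bead_j)
  if (is.null(pi_) || is.null(pj))
    stop("no diagonal parameters for pair (", bead_i, ", ", bead_j, ")")
  form <- if (bead_i == "W" || bead_j == "W") "lj12-4" else "lj9-6"
  pair_params(sigma  = (pi_$sigma + pj$sigma) / 2,
              epsilon = sqrt(pi_$epsilon * pj$epsilon),
              form = form, origin = "combination-rule")
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

ff_pair_entry <- function(ff, a, b) ff$pairs[[pair_key(a, b)]]

#' Resolve the nonbonded parameters of a bead type pair
#'
#' Applies the model's substitution rules in fixed precedence order:
#' \enumerate{
#'   \item an explicit entry in the pair table (the fitted CD cross terms
#'     and the diagonal reference values);
#'   \item similarity rules: `CD:ASP` inherits the fitted `CD:CT2`
#'     parameters (the two beads are similarly sized and the interaction is
#'     not electrostatic), and `CD:SOD` / `CD:CLA` inherit `CD:W`;
#'   \item the repulsive-core rules: any pair involving `Au` is purely
#'     repulsive with sigma 4.0 A and epsilon 0.0001 kJ/mol, and `CD:CD`
#'     is purely repulsive with sigma 2.785 A and epsilon 0.0001 kJ/mol;
#'   \item the Lorentz-Berthelot combination of the diagonal entries,
#'     flagged `origin = "combination-rule"` as an educated guess.
#' }
#' Any pair involving the water bead `W` is assigned the 12-4 form, all
#' others the 9-6 form. The function is symmetric in its first two
#' arguments.
#'
#' @param type_i,type_j Bead type labels.
#' @param ff A [forcefield] object.
#' @return A [pair_params] object.
#' @export
resolve_pair <- function(type_i, type_j, ff) {
  known <- ff$beads$name
  if (!(type_i %in% known)) stop("unknown bead type: ", type_i)
  if (!(type_j %in% known)) stop("unknown bead type: ", type_j)
  form <- if (type_i == "W" || type_j == "W") "lj12-4" else "lj9-6"

  hit <- ff_pair_entry(ff, type_i, type_j)
  if (!is.null(hit)) {
    hit$form <- form
    return(hit)
  }
  # similarity substitutions for the core-decoy bead
  sim <- ff$similarity[[pair_key(type_i, type_j)]]
  if (!is.null(sim)) {
    src <- ff_pair_entry(ff, sim[1], sim[2])
    if (!is.null(src))
      return(pair_params(src$sigma, src$epsilon, form, origin = "similarity"))
  }
  # fully repulsive core rules
  if (type_i == "Au" || type_j == "Au")
    return(pair_params(4.0, 1e-4, form, origin = "repulsive"))
  if (type_i == "CD" && type_j == "CD")
    return(pair_params(2.785, 1e-4, form, origin = "repulsive"))
  lorentz_berthelot(type_i, type_j, ff)
}

#' Force-field container
#'
#' Assembles bead, pair, bond and angle tables into a single object used by
#' the topology builder and the engine.
#'
#' @param beads `data.frame` with columns `name`, `mass` (amu),
#'   `charge` (e).
#' @param pairs Named list of [pair_params] keyed by `"A:B"` with the two
#'   labels in sorted order.
#' @param bonds Named list of [bond_params] keyed the same way.
#' @param angles Named list of [angle_params] keyed `"A:B:C"` (outer labels
#'   sorted).
#' @param similarity Named list mapping a pair key to the `c(a, b)` pair
#'   whose parameters it inherits.
#' @param dielectric Relative permittivity applied to point-charge
#'   electrostatics (the coarse-grained water bead carries no charge, so
#'   screening enters through this constant). Default 80.
#' @return An object of class `forcefield`.
#' @export
forcefield <- function(beads, pairs, bonds = list(), angles = list(),
                       similarity = list(), dielectric = 80) {
  stopifnot(is.data.frame(beads),
            all(c("name", "mass", "charge") %in% names(beads)))
  structure(list(beads = beads, pairs = pairs, bonds = bonds,
                 angles = angles, similarity = similarity,
                 dielectric = dielectric),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield: %d bead types, %d pair entries, %d bonds, %d angles>\n",
              nrow(x$beads), length(x$pairs), length(x$bonds),
              length(x$angles)))
  invisible(x)
}

ff_bond_entry <- function(ff, a, b) ff$bonds[[pair_key(a, b)]]

angle_key <- function(a, b, c) {
  ends <- sort(c(a, c))
  paste(ends[1], b, ends[2], sep = ":")
}

ff_angle_entry <- function(ff, a, b, c) ff$angles[[angle_key(a, b, c)]]

#' Read a force field from its plain-text parameter file
#'
#' One record per line; `#` starts a comment. Units in the file follow the
#' printed-table convention (sigma and bond lengths in Angstrom, epsilon in
#' kJ/mol, bond force constants in kJ/mol/A^2, angle force constants in
#' kJ/mol/rad^2, angles in degrees); bonded records are converted to the
#' internal nm units on load. Grammar:
#' \preformatted{
#' bead   <name> <mass_amu> <charge_e>
#' pair   <a> <b> <lj9-6|lj12-4> <epsilon_kJmol> <sigma_A> <origin>
#' bond   <a> <b> <k_kJmolA2> <b0_A>
#' angle  <a> <b> <c> <k_kJmolrad2> <theta0_deg>
#' similar <a> <b> from <c> <d>
#' dielectric <value>
#' }
#'
#' @param path File path.
#' @return A [forcefield] object.
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) stop("force-field file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  beads <- list(); pairs <- list(); bonds <- list(); angles <- list()
  similarity <- list(); dielectric <- 80
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    kw <- tok[1]
    if (kw == "bead") {
      if (length(tok) != 4) stop("malformed bead record: ", ln)
      beads[[tok[2]]] <- data.frame(name = tok[2],
                                    mass = as.numeric(tok[3]),
                                    charge = as.numeric(tok[4]))
    } else if (kw == "pair") {
      if (length(tok) != 7) stop("malformed pair record: ", ln)
      pairs[[pair_key(tok[2], tok[3])]] <-
        pair_params(sigma = as.numeric(tok[6]), epsilon = as.numeric(tok[5]),
                    form = tok[4], origin = tok[7])
    } else if (kw == "bond") {
      if (length(tok) != 5) stop("malformed bond record: ", ln)
      bonds[[pair_key(tok[2], tok[3])]] <-
        bond_params(k_b = as.numeric(tok[4]) * 100,  # kJ/mol/A^2 -> kJ/mol/nm^2
                    b_eq = as.numeric(tok[5]) / 10)  # A -> nm
    } else if (kw == "angle") {
      if (length(tok) != 6) stop("malformed angle record: ", ln)
      angles[[angle_key(tok[2], tok[3], tok[4])]] <-
        angle_params(k_theta = as.numeric(tok[5]), theta_eq = as.numeric(tok[6]))
    } else if (kw == "similar") {
      if (length(tok) != 6 || tok[4] != "from")
        stop("malformed similar record: ", ln)
      similarity[[pair_key(tok[2], tok[3])]] <- c(tok[5], tok[6])
    } else if (kw == "dielectric") {
      dielectric <- as.numeric(tok[2])
    } else {
      stop("unrecognised record '", kw, "' in force-field file: ", ln)
    }
  }
  if (!length(beads)) stop("force-field file defines no beads: ", path)
  bead_df <- do.call(rbind, beads)
  rownames(bead_df) <- NULL
  if (anyNA(bead_df$mass) || anyNA(bead_df$charge))
    stop("non-numeric bead record in force-field file: ", path)
  forcefield(bead_df, pairs, bonds, angles, similarity, dielectric)
}

#' Write a force field to its plain-text parameter file
#'
#' Inverse of [read_forcefield]; a read/write round trip reproduces the
#' force field exactly.
#'
#' @param ff A [forcefield] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  out <- c("# cgnp force-field parameter file",
           "# units: epsilon kJ/mol, sigma/b0 Angstrom, k_b kJ/mol/A^2,",
           "#        k_theta kJ/mol/rad^2, theta0 degrees",
           sprintf("dielectric %.17g", ff$dielectric))
  for (i in seq_len(nrow(ff$beads)))
    out <- c(out, sprintf("bead %s %.17g %.17g", ff$beads$name[i],
                          ff$beads$mass[i], ff$beads$charge[i]))
  for (k in names(ff$pairs)) {
    p <- ff$pairs[[k]]
    ab <- strsplit(k, ":", fixed = TRUE)[[1]]
    out <- c(out, sprintf("pair %s %s %s %.17g %.17g %s",
                          ab[1], ab[2], p$form, p$epsilon, p$sigma, p$origin))
  }
  for (k in names(ff$bonds)) {
    b <- ff$bonds[[k]]
    ab <- strsplit(k, ":", fixed = TRUE)[[1]]
    out <- c(out, sprintf("bond %s %s %.17g %.17g",
                          ab[1], ab[2], b$k_b / 100, b$b_eq * 10))
  }
  for (k in names(ff$angles)) {
    a <- ff$angles[[k]]
    abc <- strsplit(k, ":", fixed = TRUE)[[1]]
    out <- c(out, sprintf("angle %s %s %s %.17g %.17g",
                          abc[1], abc[2], abc[3], a$k_theta, a$theta_eq))
  }
  for (k in names(ff$similarity)) {
    ab <- strsplit(k, ":", fixed = TRUE)[[1]]
    out <- c(out, sprintf("similar %s %s from %s %s",
                          ab[1], ab[2], ff$similarity[[k]][1],
                          ff$similarity[[k]][2]))
  }
  writeLines(out, path)
  invisible(path)
}

#' The default nanoparticle force field
#'
#' Loads the parameter file shipped with the package: the fitted core-decoy
#' pair table (CD:CM, CD:CT2, CD:CM2, CD:W, CD:SOD, CD:CLA), the repulsive
#' Au/CD core rules, the CD:ASP and CD:ion similarity rules, reference
#' diagonal parameters for the shell/solvent bead types, and provisional
#' bonded terms for the OT and MUA ligand templates (see the package
#' vignette for their provenance and caveats).
#'
#' @return A [forcefield] object.
#' @export
default_forcefield <- function() {
  path <- system.file("extdata", "cgnp_default.ff", package = "cgnp")
  if (path == "") stop("shipped force-field file not found")
  read_forcefield(path)
}
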