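# R-side interface to the compiled dynamics engine.

#' Engine configuration
#'
#' @param timestep Integration time step, ps. Default 0.015 (15 fs).
#' @param temperature Thermostat target, K. Default 298.
#' @param cutoff Nonbonded truncation distance, nm. Default 1.5 (plain
#'   truncation, no switching).
#' @param friction Langevin friction, 1/ps. `0` gives symplectic NVE
#'   velocity-Verlet. Default 1.
#' @param seed Integer seed for the thermostat noise.
#' @param skin Verlet-list skin, nm. Default 0.3.
#' @param coulomb `"dsf"` (damped shifted-force within the cutoff,
#'   force-continuous at the cutoff) or `"off"`.
#' @param dsf_alpha DSF damping parameter, 1/nm. Default 2.
#' @param dielectric Relative permittivity scaling the point-charge
#'   interactions; `NULL` takes the force-field value.
#' @param lj_shift Subtract the pair energy at the cutoff so the truncated
#'   potential is continuous (LAMMPS `shift yes`); forces are unchanged.
#'   Useful for strict energy-conservation measurements. Default `FALSE`
#'   (plain truncation).
#' @param restraint_half Use the `1/2 k x^2` convention for the COM
#'   restraint instead of the default `k x^2`. Default `FALSE`.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(timestep = 0.015, temperature = 298, cutoff = 1.5,
                          friction = 1, seed = 1, skin = 0.3,
                          coulomb = c("dsf", "off"), dsf_alpha = 2,
                          dielectric = NULL, lj_shift = FALSE,
                          restraint_half = FALSE) {
  coulomb <- match.arg(coulomb)
  stopifnot(timestep > 0, cutoff > 0, friction >= 0, skin >= 0)
  structure(list(timestep = timestep, temperature = temperature,
                 cutoff = cutoff, friction = friction, seed = seed,
                 skin = skin, coulomb = coulomb, dsf_alpha = dsf_alpha,
                 dielectric = dielectric, lj_shift = isTRUE(lj_shift),
                 restraint_half = restraint_half),
            class = "engine_config")
}

#' Centre-of-mass distance restraint
#'
#' Harmonic bias `U = k (|COM_a - COM_b| - r0)^2` between the mass-weighted
#' centres of two bead groups, distributed mass-weighted over the group
#' members. With `velocity != 0` the reference distance `r0` advances
#' linearly in time (constant-velocity pulling).
#'
#' @param group_a,group_b Bead indices (1-based).
#' @param k Bias constant, kJ/mol/nm^2. Default 1300.
#' @param r0 Reference distance, nm.
#' @param velocity Pulling velocity, nm/ps. Default 0 (umbrella bias).
#' @return An object of class `com_restraint`.
#' @export
com_restraint <- function(group_a, group_b, k = 1300, r0, velocity = 0) {
  stopifnot(length(group_a) > 0, length(group_b) > 0, k > 0, r0 >= 0)
  structure(list(group_a = as.integer(group_a),
                 group_b = as.integer(group_b),
                 k = k, r0 = r0, velocity = velocity),
            class = "com_restraint")
}

#' Evaluate a COM restraint on a configuration
#'
#' Pure-R reference evaluation: returns the bias forces, the bias energy
#' and the instantaneous reaction-coordinate value (the COM distance).
#' Used for reporting and as a check of the engine's internal restraint.
#'
#' @param positions `n x 3` coordinate matrix, nm.
#' @param mass Bead masses.
#' @param box Box lengths for minimum image.
#' @param restraint A [com_restraint].
#' @param half Use the `1/2` convention. Default `FALSE`.
#' @return List with `forces` (n x 3), `energy` (kJ/mol) and
#'   `reaction_coordinate` (nm).
#' @export
restraint_force <- function(positions, mass, box, restraint, half = FALSE) {
  ca <- group_com(positions, restraint$group_a, mass, box)
  cb <- group_com(positions, restraint$group_b, mass, box)
  d <- min_image(ca - cb, box)
  r <- sqrt(sum(d^2))
  pref <- if (half) 0.5 else 1
  dr <- r - restraint$r0
  energy <- pref * restraint$k * dr^2
  forces <- matrix(0, nrow(positions), 3)
  if (r > 1e-12) {
    u <- d / r
    fmag <- -2 * pref * restraint$k * dr
    ma <- mass[restraint$group_a]; mb <- mass[restraint$group_b]
    forces[restraint$group_a, ] <-
      outer(fmag * ma / sum(ma), u)
    forces[restraint$group_b, ] <-
      outer(-fmag * mb / sum(mb), u)
  }
  list(forces = forces, energy = energy, reaction_coordinate = r)
}

# Lower a cg_system + force field into the flat arrays the compiled
# engine consumes. Rigid groups of size 1 are treated as free beads.
compile_system <- function(system, ff, config) {
  types <- sort(unique(system$type))
  ti <- match(system$type, types) - 1L
  nt <- length(types)
  sig <- matrix(0, nt, nt); eps <- matrix(0, nt, nt)
  frm <- matrix(0L, nt, nt)
  for (a in seq_len(nt)) for (b in seq_len(nt)) {
    p <- resolve_pair(types[a], types[b], ff)
    sig[a, b] <- p$sigma / 10  # Angstrom -> nm
    eps[a, b] <- p$epsilon
    frm[a, b] <- if (p$form == "lj12-4") 1L else 0L
  }
  nb <- nrow(system$bonds)
  bonds <- matrix(0L, nb, 2); bk <- numeric(nb); bb0 <- numeric(nb)
  if (nb) for (r in seq_len(nb)) {
    bp <- ff_bond_entry(ff, system$bonds$type_i[r], system$bonds$type_j[r])
    if (is.null(bp)) stop("no bond parameters for ",
                          system$bonds$type_i[r], "-", system$bonds$type_j[r])
    bonds[r, ] <- c(system$bonds$i[r] - 1L, system$bonds$j[r] - 1L)
    bk[r] <- bp$k_b; bb0[r] <- bp$b_eq
  }
  na <- nrow(system$angles)
  angles <- matrix(0L, na, 3); ak <- numeric(na); at0 <- numeric(na)
  if (na) for (r in seq_len(na)) {
    ap <- ff_angle_entry(ff, system$angles$type_i[r], system$angles$type_j[r],
                         system$angles$type_k[r])
    if (is.null(ap)) stop("no angle parameters for ",
                          system$angles$type_i[r], "-",
                          system$angles$type_j[r], "-",
                          system$angles$type_k[r])
    angles[r, ] <- c(system$angles$i[r] - 1L, system$angles$j[r] - 1L,
                     system$angles$k[r] - 1L)
    ak[r] <- ap$k_theta; at0[r] <- ap$theta_eq * pi / 180
  }
  rigid <- rep(-1L, length(system$type))
  gid <- 0L
  for (g in system$rigid_groups) {
    if (length(g) >= 2) {
      rigid[g] <- gid
      gid <- gid + 1L
    }
  }
  dielectric <- if (is.null(config$dielectric)) ff$dielectric
                else config$dielectric
  ke <- if (config$coulomb == "off" || all(system$charge == 0)) 0
        else 138.935458 / dielectric
  list(typ = ti, types = types, sigma = sig, eps = eps, form = frm,
       bonds = bonds, bond_k = bk, bond_b0 = bb0,
       angles = angles, angle_k = ak, angle_t0 = at0,
       rigid = rigid,
       cfg = list(dt = config$timestep, temperature = config$temperature,
                  friction = config$friction, cutoff = config$cutoff,
                  skin = config$skin, ke = ke,
                  dsf_alpha = config$dsf_alpha,
                  lj_shift = config$lj_shift, seed = config$seed))
}

restraint_list <- function(restraint, config) {
  if (is.null(restraint)) return(NULL)
  list(group_a = restraint$group_a, group_b = restraint$group_b,
       k = restraint$k, r0 = restraint$r0, velocity = restraint$velocity,
       half = isTRUE(config$restraint_half))
}

#' Build the nonbonded neighbour list
#'
#' All bead pairs within `cutoff + skin` under minimum image, excluding
#' 1-2 and 1-3 bonded pairs and pairs inside the same rigid group.
#'
#' @param system A `cg_system`.
#' @param cutoff Distance, nm.
#' @param skin Extra margin, nm. Default 0.
#' @return Two-column integer matrix of 1-based pair indices.
#' @export
build_neighbor_list <- function(system, cutoff, skin = 0) {
  pairs <- cpp_neighbor_pairs(system$positions, system$box, cutoff + skin)
  if (!nrow(pairs)) return(pairs)
  keep <- rep(TRUE, nrow(pairs))
  # intra-rigid exclusion
  rid <- rep(NA_integer_, length(system$type))
  for (g in seq_along(system$rigid_groups))
    rid[system$rigid_groups[[g]]] <- g
  keep <- keep & !(!is.na(rid[pairs[, 1]]) & !is.na(rid[pairs[, 2]]) &
                     rid[pairs[, 1]] == rid[pairs[, 2]])
  # bonded 1-2 / 1-3 exclusions
  n <- length(system$type)
  pk <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)
  ex <- c(if (nrow(system$bonds)) pk(system$bonds$i, system$bonds$j),
          if (nrow(system$angles)) c(pk(system$angles$i, system$angles$j),
                                     pk(system$angles$j, system$angles$k),
                                     pk(system$angles$i, system$angles$k)))
  if (length(ex))
    keep <- keep & !(pk(pairs[, 1], pairs[, 2]) %in% ex)
  pairs[keep, , drop = FALSE]
}

#' Compute forces and the potential-energy decomposition
#'
#' Single-point evaluation of all force-field terms on the current
#' configuration: per-term energies (bond, angle, LJ, Coulomb, restraint)
#' and per-bead forces. Newton's third law holds exactly; pairs inside a
#' rigid group are skipped.
#'
#' @param system A `cg_system`.
#' @param ff A [forcefield].
#' @param config An [engine_config].
#' @param restraint Optional [com_restraint].
#' @param velocities Optional `n x 3` matrix (unused by the evaluation,
#'   kept for interface symmetry).
#' @return List with `forces` (n x 3, kJ/mol/nm) and `energy` (named
#'   list: bond, angle, lj, coulomb, restraint, total), plus the
#'   instantaneous `reaction_coordinate` when a restraint is given.
#' @export
compute_forces <- function(system, ff, config = engine_config(),
                           restraint = NULL, velocities = NULL) {
  cs <- compile_system(system, ff, config)
  n <- length(system$type)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  out <- cpp_compute_forces(system$positions, velocities,
                            system$mass, system$charge, system$box,
                            cs$typ, cs$sigma, cs$eps, cs$form,
                            cs$bonds, cs$bond_k, cs$bond_b0,
                            cs$angles, cs$angle_k, cs$angle_t0,
                            cs$rigid, cs$cfg,
                            restraint_list(restraint, config))
  energy <- list(bond = out$bond, angle = out$angle, lj = out$lj,
                 coulomb = out$coulomb, restraint = out$restraint)
  energy$total <- sum(unlist(energy))
  list(forces = out$forces, energy = energy,
       reaction_coordinate = out$reaction_coordinate)
}

#' Maxwell-Boltzmann initial velocities
#'
#' @param system A `cg_system`.
#' @param temperature K.
#' @param seed Integer seed.
#' @return `n x 3` velocity matrix, nm/ps.
#' @export
maxwell_velocities <- function(system, temperature, seed = 1) {
  n <- length(system$mass)
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n), n, 3) *
      sqrt(KB_KJ * temperature / system$mass)
    sweep(v, 2, colMeans(v * system$mass) * n / sum(system$mass))
  })
}

#' Run coarse-grained dynamics
#'
#' Velocity-Verlet integration with optional Langevin thermostatting;
#' nanoparticle cores propagate as torque-driven rigid bodies
#' (quaternion orientation, body-frame inertia). Frames and an energy
#' log are emitted every `stride` steps.
#'
#' @param system A `cg_system`.
#' @param ff A [forcefield].
#' @param config An [engine_config].
#' @param n_steps Number of integration steps.
#' @param stride Reporting stride in steps. Default 10.
#' @param restraint Optional [com_restraint] (umbrella bias or pulling).
#' @param velocities Optional initial velocities; default drawn from the
#'   Maxwell-Boltzmann distribution at the target temperature (seeded),
#'   or zeros when `friction = 0` and `temperature = 0`.
#' @return List with `trajectory` (a [cg_trajectory]), `energies`
#'   (`data.frame` log: per-term energies, temperature, reaction
#'   coordinate) and `final` (positions, velocities, final restraint
#'   centre).
#' @export
run_md <- function(system, ff, config = engine_config(), n_steps,
                   stride = 10, restraint = NULL, velocities = NULL) {
  cs <- compile_system(system, ff, config)
  if (is.null(velocities)) {
    velocities <- if (config$temperature > 0)
      maxwell_velocities(system, config$temperature, config$seed)
    else matrix(0, length(system$mass), 3)
  }
  out <- cpp_run_md(system$positions, velocities,
                    system$mass, system$charge, system$box,
                    cs$typ, cs$sigma, cs$eps, cs$form,
                    cs$bonds, cs$bond_k, cs$bond_b0,
                    cs$angles, cs$angle_k, cs$angle_t0,
                    cs$rigid, cs$cfg,
                    restraint_list(restraint, config),
                    as.integer(n_steps), as.integer(stride))
  nrec <- length(out$times)
  coords <- array(out$frames, dim = c(length(system$type), 3, nrec))
  traj <- cg_trajectory(coords, system$box, times = out$times,
                        type = system$type, mass = system$mass)
  energies <- as.data.frame(out$energies)
  list(trajectory = traj, energies = energies,
       final = list(positions = out$positions,
                    velocities = out$velocities,
                    r0 = out$r0_final))
}
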