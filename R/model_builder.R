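# Construction of coarse-grained nanoparticle topologies: the rigid Au/CD
# core, grafted ligand shells, lattices of NPs, solvent and ions.

GOLDEN <- (1 + sqrt(5)) / 2

.cgnp_env <- new.env(parent = emptyenv())

ff_default_cached <- function() {
  if (is.null(.cgnp_env$default_ff))
    .cgnp_env$default_ff <- default_forcefield()
  .cgnp_env$default_ff
}

# Evenly distributed points on a sphere of radius r (spherical Fibonacci
# lattice); `offset` rotates the azimuthal phase so distinct seeds give
# distinct but equally uniform layouts.
fibonacci_sphere <- function(n, r, offset = 0) {
  if (n == 1L) return(matrix(c(0, 0, r), 1, 3))
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * GOLDEN + offset
  rho <- sqrt(pmax(0, 1 - z^2))
  r * cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Build a rigid nanoparticle core
#'
#' Generates the Au/CD core geometry: `n_cd` grafting (core-decoy) beads
#' evenly distributed on the outer spherical shell via a deterministic
#' spherical-Fibonacci layout, and `n_au` gold beads filling concentric
#' inner shells. The whole core is marked rigid; because all interactions
#' involving the core are carried by the CD beads alone (Au is purely
#' repulsive and the core is interaction-excluded internally), only the CD
#' shell geometry matters energetically, and the generated core is a
#' faithful stand-in for an externally determined structure with the same
#' bead counts and shell radius.
#'
#' @param n_au Number of gold beads (`>= 0`). Default 144.
#' @param n_cd Number of core-decoy grafting beads (`>= 1`). Default 60.
#' @param radius Radius of the CD shell in nm. Default 1.0.
#' @param seed Integer controlling the azimuthal phase of the layout;
#'   identical seeds give bit-identical cores.
#' @param coords Optional externally supplied core coordinates overriding
#'   generation: a numeric matrix with `n_au + n_cd` rows (nm), gold beads
#'   first, then CD beads.
#' @return An object of class `cg_core`: list with `positions` (n x 3
#'   matrix, nm), `type` (`"Au"`/`"CD"`), `rigid` (indices of the rigid
#'   group: all beads), `radius` and `seed`.
#' @export
build_core <- function(n_au = 144, n_cd = 60, radius = 1.0, seed = 0,
                       coords = NULL) {
  if (n_au < 0) stop("n_au must be non-negative")
  if (n_cd < 1) stop("n_cd must be at least 1")
  n_au <- as.integer(n_au); n_cd <- as.integer(n_cd)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_au + n_cd || ncol(coords) != 3)
      stop("coords must be a (n_au + n_cd) x 3 matrix")
    pos <- coords
  } else {
    offset <- 2 * pi * ((seed * (GOLDEN - 1)) %% 1)
    if (n_cd == 1L && n_au == 0L) {
      pos <- matrix(0, 1, 3)  # degenerate single-CD core at the origin
    } else {
      cd_pos <- fibonacci_sphere(n_cd, radius, offset)
      au_pos <- NULL
      if (n_au > 0L) {
        pitch <- 0.25  # inner packing pitch, nm; the core is a rigid,
                       # interaction-excluded scaffold, so this mimics the
                       # compact metallic interior rather than the pair sigma
        radii <- seq(radius - pitch, 0, by = -pitch)
        radii <- radii[radii > pitch / 2]
        caps <- pmax(1L, as.integer(floor(4 * pi * radii^2 / pitch^2)))
        capacity <- sum(caps) + 1L  # +1 for the origin
        if (n_au > capacity)
          stop("radius too small to place ", n_au,
               " Au beads without overlap (capacity ", capacity, ")")
        remaining <- n_au
        shells <- list()
        for (k in seq_along(radii)) {
          take <- min(caps[k], remaining)
          if (take > 0L)
            shells[[length(shells) + 1L]] <-
              fibonacci_sphere(take, radii[k], offset + k)
          remaining <- remaining - take
          if (remaining == 0L) break
        }
        if (remaining > 0L)
          shells[[length(shells) + 1L]] <- matrix(0, 1, 3)
        au_pos <- do.call(rbind, shells)
      }
      pos <- rbind(au_pos, cd_pos)
    }
  }
  dimnames(pos) <- NULL
  structure(list(positions = pos,
                 type = c(rep("Au", n_au), rep("CD", n_cd)),
                 rigid = seq_len(n_au + n_cd),
                 radius = radius, seed = seed),
            class = "cg_core")
}

#' @export
print.cg_core <- function(x, ...) {
  cat(sprintf("<cg_core: %d Au + %d CD beads, shell radius %.2f nm>\n",
              sum(x$type == "Au"), sum(x$type == "CD"), x$radius))
  invisible(x)
}

#' Ligand templates
#'
#' Coarse-grained mapping of the two shipped ligands, listed from the
#' grafting point outward (the grafting CD bead itself belongs to the
#' core). Octanethiol (OT) maps to three CM2 beads and a terminal CT2;
#' 11-mercaptoundecanoic acid (MUA) maps to two CM2, two CM and a terminal
#' (deprotonated, -1 charged) ASP bead. Bonds link consecutive beads
#' (including the CD-A grafting bond) and angles span consecutive triples.
#'
#' @return An object of class `ligand_template` with fields `name` and
#'   `bead_sequence`.
#' @export
ot_template <- function() {
  structure(list(name = "OT", bead_sequence = c("CM2", "CM2", "CM2", "CT2")),
            class = "ligand_template")
}

#' @rdname ot_template
#' @export
mua_template <- function() {
  structure(list(name = "MUA", bead_sequence = c("CM2", "CM2", "CM", "CM", "ASP")),
            class = "ligand_template")
}

bead_property <- function(ff, types, what) {
  idx <- match(types, ff$beads$name)
  if (anyNA(idx)) stop("unknown bead type: ",
                       paste(unique(types[is.na(idx)]), collapse = ", "))
  ff$beads[[what]][idx]
}

#' Graft ligands onto a nanoparticle core
#'
#' Assigns exactly one ligand to every CD bead. Template identity is a
#' seeded random permutation of the requested composition; ligand beads
#' are placed radially outward from their CD bead at the equilibrium bond
#' lengths of the force field (initial conformations are straight chains;
#' relaxation is the engine's job). The CD-A grafting bond and the CD-A-B
#' angle are instantiated together with the intra-ligand bonded terms.
#'
#' @param core A [build_core] result.
#' @param templates List of [ligand_template] objects.
#' @param fractions Numeric vector, same length, summing to 1; each
#'   `fraction * n_cd` must be a whole number.
#' @param seed Integer seed for the assignment permutation.
#' @param ff Force field supplying masses, charges and equilibrium bond
#'   lengths. Default [default_forcefield()].
#' @return An object of class `np_topology`: positions, types, charges,
#'   masses, bond and angle tables, the rigid core group, per-ligand
#'   records and the composition.
#' @export
graft_ligands <- function(core, templates, fractions, seed = 1,
                          ff = ff_default_cached()) {
  stopifnot(inherits(core, "cg_core"))
  if (length(templates) != length(fractions))
    stop("templates and fractions differ in length")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_cd <- sum(core$type == "CD")
  counts <- fractions * n_cd
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("non-integral ligand counts: fractions ",
         paste(fractions, collapse = ", "), " of ", n_cd, " CD beads")
  counts <- as.integer(round(counts))

  assignment <- rep(seq_along(templates), counts)
  assignment <- withr::with_seed(seed, sample(assignment))

  cd_idx <- which(core$type == "CD")
  n_core <- nrow(core$positions)
  positions <- core$positions
  types <- core$type
  bonds <- list(); angles <- list(); ligands <- list()

  for (li in seq_len(n_cd)) {
    tmpl <- templates[[assignment[li]]]
    cd <- cd_idx[li]
    u <- core$positions[cd, ]
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-12) c(0, 0, 1) else u / nu
    seqb <- tmpl$bead_sequence
    chain_types <- c("CD", seqb)
    # cumulative equilibrium bond lengths along the radial direction
    b0 <- vapply(seq_along(seqb), function(k) {
      bp <- ff_bond_entry(ff, chain_types[k], chain_types[k + 1])
      if (is.null(bp)) stop("no bond parameters for ",
                            chain_types[k], "-", chain_types[k + 1])
      bp$b_eq
    }, numeric(1))
    offs <- cumsum(b0)
    new_idx <- nrow(positions) + seq_along(seqb)
    positions <- rbind(positions,
                       t(vapply(offs, function(d) core$positions[cd, ] + d * u,
                                numeric(3))))
    types <- c(types, seqb)
    chain_idx <- c(cd, new_idx)
    for (k in seq_along(seqb))
      bonds[[length(bonds) + 1L]] <-
        data.frame(i = chain_idx[k], j = chain_idx[k + 1],
                   type_i = chain_types[k], type_j = chain_types[k + 1])
    if (length(chain_idx) >= 3)
      for (k in seq_len(length(chain_idx) - 2))
        angles[[length(angles) + 1L]] <-
          data.frame(i = chain_idx[k], j = chain_idx[k + 1], k = chain_idx[k + 2],
                     type_i = chain_types[k], type_j = chain_types[k + 1],
                     type_k = chain_types[k + 2])
    ligands[[li]] <- list(template = tmpl$name, cd = cd, beads = new_idx)
  }
  dimnames(positions) <- NULL
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), type_i = character(),
               type_j = character())
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(),
               type_i = character(), type_j = character(),
               type_k = character())
  frac_ot <- if (any(vapply(templates, `[[`, "", "name") == "OT"))
    counts[which(vapply(templates, `[[`, "", "name") == "OT")[1]] / n_cd else 0
  structure(list(positions = positions, type = types,
                 charge = bead_property(ff, types, "charge"),
                 mass = bead_property(ff, types, "mass"),
                 bonds = bonds, angles = angles,
                 rigid_group = seq_len(n_core),
                 ligands = ligands, composition = frac_ot,
                 core_radius = core$radius),
            class = "np_topology")
}

#' @export
print.np_topology <- function(x, ...) {
  cat(sprintf(
    "<np_topology: %d beads (%d core), %d ligands, net charge %+g e>\n",
    length(x$type), length(x$rigid_group), length(x$ligands),
    sum(x$charge)))
  invisible(x)
}

#' Terminal ligand-shell beads of a nanoparticle
#'
#' Index of the outermost bead of every ligand (the shell-RDF target
#' group of the parameterization protocol).
#'
#' @param np An `np_topology`.
#' @param offset Index offset when the nanoparticle is embedded in a
#'   larger system. Default 0.
#' @return Integer vector, one index per ligand.
#' @export
terminal_beads <- function(np, offset = 0L) {
  vapply(np$ligands, function(l) l$beads[length(l$beads)], integer(1)) + offset
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rand_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_mat(q / sqrt(sum(q^2)))
}

empty_system <- function(box) {
  structure(list(positions = matrix(numeric(0), 0, 3), type = character(),
                 charge = numeric(), mass = numeric(), molecule = integer(),
                 bonds = data.frame(i = integer(), j = integer(),
                                    type_i = character(), type_j = character()),
                 angles = data.frame(i = integer(), j = integer(), k = integer(),
                                     type_i = character(), type_j = character(),
                                     type_k = character()),
                 rigid_groups = list(), box = box, periodic = TRUE,
                 nps = list(), solvent_idx = integer()),
            class = "cg_system")
}

#' Place nanoparticle copies on a cubic lattice
#'
#' Replicates a nanoparticle topology on an `n_side^3` cubic lattice with
#' the given spacing, centred in the box, applying an independent seeded
#' random rigid rotation to each copy (the grafting geometry is random, so
#' copies must not be orientationally correlated).
#'
#' @param np A [graft_ligands] topology (or a bare [build_core] promoted to
#'   a ligand-free topology is not supported; graft first).
#' @param n_side Lattice points per box edge (`>= 1`).
#' @param spacing Lattice constant in nm.
#' @param box Orthogonal box lengths in nm (length 1 or 3).
#' @param seed Integer seed for the per-copy rotations.
#' @return A `cg_system` with `n_side^3` molecules, periodic boundaries
#'   and per-copy rigid core groups.
#' @export
place_lattice <- function(np, n_side, spacing, box, seed = 1) {
  stopifnot(inherits(np, "np_topology"), n_side >= 1)
  box <- rep(as.numeric(box), length.out = 3)
  if (n_side > 1 && n_side * spacing > min(box) + 1e-9)
    stop("box too small for the lattice: extent ", n_side * spacing,
         " nm exceeds ", min(box), " nm")
  sys <- empty_system(box)
  core_com <- colSums(np$positions[np$rigid_group, , drop = FALSE] *
                        np$mass[np$rigid_group]) / sum(np$mass[np$rigid_group])
  centred <- sweep(np$positions, 2, core_com)
  start <- (box - n_side * spacing) / 2 + spacing / 2
  n_bead <- nrow(np$positions)
  rots <- withr::with_seed(seed,
    lapply(seq_len(n_side^3), function(i) rand_rotation()))
  m <- 0L
  pos_list <- list()
  for (ix in seq_len(n_side)) for (iy in seq_len(n_side)) for (iz in seq_len(n_side)) {
    m <- m + 1L
    centre <- start + spacing * (c(ix, iy, iz) - 1)
    pos_list[[m]] <- centred %*% t(rots[[m]]) +
      matrix(centre, n_bead, 3, byrow = TRUE)
    off <- (m - 1L) * n_bead
    if (nrow(np$bonds)) {
      b <- np$bonds; b$i <- b$i + off; b$j <- b$j + off
      sys$bonds <- rbind(sys$bonds, b)
    }
    if (nrow(np$angles)) {
      a <- np$angles; a$i <- a$i + off; a$j <- a$j + off; a$k <- a$k + off
      sys$angles <- rbind(sys$angles, a)
    }
    sys$rigid_groups[[m]] <- np$rigid_group + off
    sys$nps[[m]] <- list(beads = off + seq_len(n_bead),
                         core = off + np$rigid_group,
                         composition = np$composition)
  }
  sys$positions <- do.call(rbind, pos_list)
  dimnames(sys$positions) <- NULL
  sys$type <- rep(np$type, n_side^3)
  sys$charge <- rep(np$charge, n_side^3)
  sys$mass <- rep(np$mass, n_side^3)
  sys$molecule <- rep(seq_len(n_side^3), each = n_bead)
  rownames(sys$bonds) <- NULL; rownames(sys$angles) <- NULL
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(
    "<cg_system: %d beads, %d NPs, %d solvent/ion beads, box %.1f x %.1f x %.1f nm>\n",
    length(x$type), length(x$nps),
    length(x$type) - sum(lengths(lapply(x$nps, `[[`, "beads"))),
    x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

min_image_dist2 <- function(p, q, box) {
  d <- abs(p - q)
  d <- d - box * round(d / box)
  sum(d * d)
}

#' Solvate a system with coarse-grained water
#'
#' Places solvent beads on a jittered cubic grid, excluding sites within an
#' exclusion radius of any existing (solute) bead under minimum-image
#' convention. The default exclusion radius (0.35 nm) is about 0.9 of the
#' smallest solvent-involving sigma, preventing integrator blow-up on the
#' first step.
#'
#' @param system A `cg_system`.
#' @param solvent Bead type label, default `"W"`.
#' @param count Number of solvent beads to place. Exactly this many are
#'   placed or an error is raised.
#' @param density Alternative to `count`: target number density in
#'   beads/nm^3 (coarse-grained water at ambient conditions is about 11.1
#'   beads/nm^3 with a 3:1 mapping).
#' @param exclusion Exclusion radius in nm. Default 0.35.
#' @param seed Integer seed for the grid jitter.
#' @param ff Force field supplying the solvent mass/charge.
#' @return The solvated `cg_system`; placed solvent indices are recorded in
#'   `$solvent_idx`.
#' @export
solvate <- function(system, solvent = "W", count = NULL, density = NULL,
                    exclusion = 0.35, seed = 1, ff = ff_default_cached()) {
  stopifnot(inherits(system, "cg_system"))
  box <- system$box
  if (any(box <= 0)) stop("box has non-positive extent; cannot solvate")
  v <- prod(box)
  if (is.null(count)) {
    if (is.null(density)) stop("give either count or density")
    count <- round(density * v)
  }
  count <- as.integer(count)
  if (count == 0L) return(system)
  solute <- system$positions
  pitch <- (v / count)^(1 / 3)
  for (attempt in 1:6) {
    ng <- pmax(1L, as.integer(floor(box / pitch)))
    gx <- (seq_len(ng[1]) - 0.5) * box[1] / ng[1]
    gy <- (seq_len(ng[2]) - 0.5) * box[2] / ng[2]
    gz <- (seq_len(ng[3]) - 0.5) * box[3] / ng[3]
    sites <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    dimnames(sites) <- NULL
    jit <- withr::with_seed(seed + attempt - 1L,
      matrix(stats::runif(length(sites), -0.15, 0.15), nrow(sites), 3))
    sites <- sites + jit * matrix(box / ng, nrow(sites), 3, byrow = TRUE)
    sites <- sites %% matrix(box, nrow(sites), 3, byrow = TRUE)
    if (nrow(solute)) {
      keep <- rep(TRUE, nrow(sites))
      ex2 <- exclusion^2
      for (s in seq_len(nrow(solute))) {
        d <- sweep(sites, 2, solute[s, ])
        d <- abs(d)
        d <- d - matrix(box, nrow(sites), 3, byrow = TRUE) *
          round(d / matrix(box, nrow(sites), 3, byrow = TRUE))
        keep <- keep & (rowSums(d * d) > ex2)
      }
      sites <- sites[keep, , drop = FALSE]
    }
    if (nrow(sites) >= count) {
      sites <- sites[seq_len(count), , drop = FALSE]
      n0 <- length(system$type)
      system$positions <- rbind(system$positions, sites)
      dimnames(system$positions) <- NULL
      system$type <- c(system$type, rep(solvent, count))
      system$charge <- c(system$charge,
                         rep(bead_property(ff, solvent, "charge"), count))
      system$mass <- c(system$mass,
                       rep(bead_property(ff, solvent, "mass"), count))
      mol0 <- if (length(system$molecule)) max(system$molecule) else 0L
      system$molecule <- c(system$molecule, mol0 + seq_len(count))
      system$solvent_idx <- c(system$solvent_idx, n0 + seq_len(count))
      return(system)
    }
    pitch <- pitch * 0.92  # denser candidate grid, retry
  }
  stop("could not place ", count, " solvent beads without overlaps")
}

#' Neutralize a system and add salt
#'
#' First adds counterions (SOD for a negative solute, CLA for a positive
#' one) to bring the total charge to exactly zero, then adds SOD/CLA pairs
#' to reach the requested salt concentration. The pair count is
#' `round(concentration * 0.6022 nm^-3/M * box volume)` (Avogadro
#' conversion); counterions are counted separately from salt. Ions replace
#' randomly chosen solvent beads (seeded).
#'
#' @param system A solvated `cg_system`.
#' @param concentration Salt concentration in mol/L. Default 0 (neutralize
#'   only).
#' @param seed Integer seed for the replacement choice.
#' @param ff Force field supplying ion masses/charges.
#' @return The neutralized `cg_system`.
#' @export
neutralize_and_salt <- function(system, concentration = 0, seed = 1,
                                ff = ff_default_cached()) {
  stopifnot(inherits(system, "cg_system"))
  q <- sum(system$charge)
  n_counter <- as.integer(round(abs(q)))
  counter_type <- if (q < 0) "SOD" else "CLA"
  n_pairs <- as.integer(round(concentration * 0.6022140857 * prod(system$box)))
  n_ions <- n_counter + 2L * n_pairs
  if (n_ions == 0L) return(system)
  if (length(system$solvent_idx) < n_ions)
    stop("not enough solvent beads (", length(system$solvent_idx),
         ") to place ", n_ions, " ions")
  pick <- withr::with_seed(seed, sample(system$solvent_idx, n_ions))
  new_types <- c(rep(counter_type, n_counter),
                 rep(c("SOD", "CLA"), each = n_pairs))
  system$type[pick] <- new_types
  system$charge[pick] <- bead_property(ff, new_types, "charge")
  system$mass[pick] <- bead_property(ff, new_types, "mass")
  system$solvent_idx <- setdiff(system$solvent_idx, pick)
  system
}
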