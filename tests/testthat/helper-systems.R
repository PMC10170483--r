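# Shared fixtures built in code: tiny nanoparticles, fluids and oracles.

tiny_np <- function(fractions = 1.0,
                    templates = list(ot_template()),
                    n_au = 12, n_cd = 12, radius = 0.5, seed = 0) {
  core <- build_core(n_au, n_cd, radius = radius, seed = seed)
  graft_ligands(core, templates, fractions, seed = seed + 1)
}

solvated_np_system <- function(np, box = 4.5, n_w = 250, seed = 2) {
  sys <- place_lattice(np, 1, 1, box, seed = 1)
  solvate(sys, count = n_w, seed = seed, exclusion = 0.4)
}

w_fluid <- function(n = 200, box = 4, seed = 7) {
  solvate(cgnp:::empty_system(rep(box, 3)), count = n, seed = seed)
}

# relax a configuration with an overdamped Langevin run
relax_system <- function(sys, ff, n_steps = 2000, seed = 2) {
  cfg <- engine_config(timestep = 0.002, friction = 20, seed = seed)
  r <- run_md(sys, ff, cfg, n_steps, stride = n_steps)
  sys$positions <- r$final$positions
  list(system = sys, velocities = r$final$velocities)
}

# O(N^2) union-find connected components: the independent cluster oracle
uf_components <- function(centers, cutoff, box = NULL) {
  n <- nrow(centers)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (is.null(box)) box <- rep(1e12, 3)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    d <- abs(centers[i, ] - centers[j, ])
    d <- d - box * round(d / box)
    if (sum(d^2) <= cutoff^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# canonical labelling so two partitions compare equal
canon_partition <- function(m) match(m, unique(m))
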