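# End-to-end grid-search recovery fixture: a frozen mini nanoparticle in a
# dilute probe solvent, with the CD:W pair placed at a known optimum at
# the centre of a 5 x 5 search grid. The whole NP is held rigid so the
# shell feature is noise-free and the solvent feature directly images the
# CD:W contact well. See the methods vignette for the reasoning behind
# the state point and the fit settings.
grid_recovery_run <- function(seed = 11) {
  ff <- default_forcefield()
  core <- build_core(8, 10, radius = 0.45, seed = 0)
  np <- graft_ligands(core, list(ot_template()), 1.0, seed = 1)
  sys <- place_lattice(np, 1, 1, 4.0, seed = 1)
  sys <- solvate(sys, count = 150, seed = 2, exclusion = 0.38)
  sys$rigid_groups <- list(seq_len(length(np$type)))
  sys$bonds <- sys$bonds[0, ]
  sys$angles <- sys$angles[0, ]
  # weakly self-interacting probe solvent: W-W clustering would otherwise
  # mask the CD:W signal at this dilution
  ff$pairs[["W:W"]] <- pair_params(4.371, 1.2, "lj12-4", "reference")
  sstar <- 3.8; estar <- 5.0
  ff$pairs[["CD:W"]] <- pair_params(sstar, estar, "lj12-4", "fitted")
  cfg <- engine_config(timestep = 0.01, friction = 5, cutoff = 1.2,
                       seed = 42)
  pre <- run_md(sys, ff, cfg, 3000, stride = 3000)
  sys$positions <- pre$final$positions
  mk_sim <- function(replicas)
    make_np_feature_simulator(sys, ff, pair = c("CD", "W"),
                              shell_group = terminal_beads(np),
                              config = cfg, n_equil = 600,
                              n_prod = 15000, stride = 10,
                              bin_width = 0.05, r_max = 1.2,
                              r_max_shell = 1.9, replicas = replicas)
  target <- mk_sim(4)(sstar, estar, seed = seed + 7777)
  grid <- interaction_grid(seq(0.9, 1.1, 0.05) * sstar,
                           seq(0.5, 1.5, 0.25) * estar, "CD:W")
  res <- derive_pair_parameters(grid, mk_sim(2), target, seed = seed,
                                degrees = 2, transform = "log",
                                clip_quantile = 0.9, log_epsilon = TRUE)
  list(result = res, grid = grid, sigma_true = sstar, epsilon_true = estar,
       sigma_step = 0.05 * sstar, epsilon_step = 0.25 * estar)
}
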