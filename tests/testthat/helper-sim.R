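# Shared miniature configurations and cached simulations. Stacks used by
# several tests are simulated once per test run and memoised here.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_size = 64, n_frames = 40, rng_seed = 101,
                   reference_photoelectrons_per_pixel = 200,
                   sample_to_reference_ratio = 0.1)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# standard noisy 64 px stack + its dc-pair reconstruction
noisy_recon <- function() {
  cached_sim("noisy_recon", function() {
    cfg <- tiny_config(n_frames = 120, rng_seed = 2024)
    fs <- simulate_stack(cfg)
    masks <- default_masks(cfg)
    list(cfg = cfg, fs = fs, masks = masks,
         recon = reconstruct_s1(fs, "dc_pair", masks, mtf = cfg$fill_factor))
  })
}
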