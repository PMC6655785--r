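# Synthetic pairs are generated once per test run and memoised; every
# fixture is built by the package's own generator at test time (no stored
# image data).

.fixture_cache <- new.env(parent = emptyenv())

fixture_pair <- function(name, spec) {
  if (!exists(name, envir = .fixture_cache)) {
    out <- generate_pair(spec, file.path(tempdir(), paste0("fix_", name)))
    out$fixed_img <- open_pyramid(out$fixed)
    out$floating_img <- open_pyramid(out$floating)
    assign(name, out, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the workhorse small pair: 512^2, 3 levels, moderate shift and difficulty
small_pair <- function() {
  fixture_pair("small", synthetic_spec(
    level0_size = c(512, 512), downsamples = c(1, 2, 4),
    true_dx0 = 20, true_dy0 = -14, cell_density = 2,
    blank_region_fraction = 0.1, noise_sigma = 3, seed = 101))
}

# 1024^2 four-level pair with the canonical 1:4:16:32 layout
pyramid_pair <- function() {
  fixture_pair("pyr4", synthetic_spec(
    level0_size = c(1024, 1024), downsamples = c(1, 4, 16, 32),
    true_dx0 = 96, true_dy0 = -64, cell_density = 2,
    blank_region_fraction = 0.15, noise_sigma = 4, seed = 202))
}
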