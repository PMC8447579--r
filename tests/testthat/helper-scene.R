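# shared fixtures, built once per test run; everything is generated in code
scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, ...) {
  if (is.null(scene_cache[[key]])) {
    scene_cache[[key]] <- simulate_scene(...)
  }
  scene_cache[[key]]
}

tiny_scene <- function() {
  cached_scene("tiny", nx = 24, ny = 24, seed = 101)
}

noisy_scene <- function() {
  cached_scene("noisy", nx = 32, ny = 32, seed = 202, snr = 250)
}

# a single-overpass truth table with hand-set values, for forward-model tests
manual_truth <- function(sif_canopy, fapar_chl = 0.6, fesc = 0.6,
                         par_mw = 4e5, time = 12.5) {
  n <- length(sif_canopy)
  nx <- n
  soil <- sif_canopy == 0 & fapar_chl == 0
  tibble::tibble(
    overpass = 1L, time = time,
    pixel = seq_len(n),
    x = seq_len(nx) - 0.5, y = 0.5,
    field = "F", crop = "manual", soil = soil,
    par_mw = par_mw,
    fapar_chl = fapar_chl,
    fapar_green = fapar_chl / 0.79,
    fesc = ifelse(soil, NA_real_, fesc),
    eps_true = ifelse(fapar_chl > 0, sif_canopy * pi / fesc / fapar_chl / par_mw, 0),
    sif_leaf = ifelse(soil, 0, sif_canopy * pi / fesc),
    sif_canopy = sif_canopy
  )
}
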