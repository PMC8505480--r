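# Shared fixtures, built once per test run.

fx <- local({
  sens <- default_sensitivities()
  device <- make_synthetic_device(seed = 1)
  pair <- solve_background_pair(device, sens, target_contrast = 3.5)
  spec_low <- solve_flicker_modulation(device, sens, pair$low_settings)
  spec_high <- solve_flicker_modulation(device, sens, pair$high_settings)
  list(sens = sens, device = device, pair = pair,
       spec_low = spec_low, spec_high = spec_high,
       designs = list(low = list(device = device, spec = spec_low),
                      high = list(device = device, spec = spec_high)))
})

# A flat-spectrum / flat-sensitivity toy on an 11-point grid (step 10 nm),
# where the rectangle rule can be summed by hand.
toy_grid <- seq(400, 500, by = 10)
toy_sens_flat <- receptor_sensitivities(
  toy_grid, matrix(1, length(toy_grid), 4,
                   dimnames = list(NULL, c("L", "M", "S", "Mel"))))

# Named excitation vector shortcut.
exc_vec <- function(L, M, S, Mel = 1) c(L = L, M = M, S = S, Mel = Mel)

# Deterministic scripted "observer": replays a fixed correctness sequence.
scripted_callback <- function(corrects) {
  i <- 0L
  function(contrast, target_interval) {
    i <<- i + 1L
    ok <- corrects[[i]]
    list(response_interval = if (ok) target_interval else 3L - target_interval,
         correct = ok)
  }
}
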