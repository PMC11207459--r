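## Shared small fixtures, built once per test run.

quiet_cfg <- function(duration_s = 6, ...) {
  phantom_config(duration_s = duration_s,
                 deep_breath_times = numeric(0),
                 cough_times = numeric(0),
                 contraction_times = numeric(0), ...)
}

## tiny static phantom with a single configurable reflector
single_reflector_phantom <- function(depth_mm = 50, duration_s = 1) {
  ph <- make_breathing_phantom(quiet_cfg(duration_s, resp_amplitude_mm = 0),
                               seed = 99)
  ph$reflectors <- data.frame(depth_mm = depth_mm, amp = 1, mode = "static",
                              stringsAsFactors = FALSE)
  ph$scatterers <- ph$scatterers[0, ]
  ph
}

## pooled-variance two-sample t-test, textbook formula (test oracle)
t_test_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = na + nb - 2)
  list(t = tstat, p = p)
}
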