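# Fixture builders shared across test files.

interval_frame <- function(t, ivl, units = "ms") {
  out <- data.frame(t = t, ivl = ivl, gap_before = FALSE)
  attr(out, "units") <- units
  class(out) <- c("filtered_intervals", "data.frame")
  out
}

# RR series sinusoidally modulated at f_mod Hz, long enough for several
# 300-s spectral windows.
modulated_rr <- function(f_mod, amp = 50, base = 800, n = 3000) {
  t <- cumsum(rep(base / 1000, n))
  interval_frame(t, base + amp * sin(2 * pi * f_mod * t))
}

# quiet one-night synthesis helpers
quiet_night <- function(ahi = 0, noise = 0, duration = 600, seed = 11,
                        fs = 125) {
  spec <- subject_spec("T01", ahi = ahi, noise_level = noise, seed = seed)
  ev <- schedule_apneas(spec, duration)
  list(spec = spec, events = ev,
       ecg = synthesize_ecg(spec, ev, fs = fs, duration = duration))
}
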