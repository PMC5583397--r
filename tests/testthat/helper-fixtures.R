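# Fixtures are built in code; no binary test data.

# band-limited random texture (thin wrapper with a fixed default seed)
make_texture <- function(seed = 42, size = 128, corr = 1.2)
  generate_texture(seed, size, correlation_length = corr)

# circularly shift matrix content by (dy, dx): the pattern moves down/right
circ_shift <- function(m, dy, dx) {
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

# small, fast PIV configuration for tests
test_cfg <- function(...) {
  defaults <- list(coarse_tile = 32L, coarse_search = 8L,
                   fine_tile = 16L, fine_search = 3L)
  do.call(piv_config, utils::modifyList(defaults, list(...)))
}

# brute-force oracle for best_match_displacement: score every shift in R
bf_best_match <- function(frame_a, frame_b, center, tile, search,
                          predicted = c(0, 0), zero_mean = TRUE) {
  half <- tile %/% 2
  ys <- (center[2] - half):(center[2] + (tile - half) - 1)
  xs <- (center[1] - half):(center[1] + (tile - half) - 1)
  if (min(ys) < 1 || min(xs) < 1 || max(ys) > nrow(frame_a) || max(xs) > ncol(frame_a))
    return(list(ux = NA, uy = NA, valid = FALSE))
  ta <- frame_a[ys, xs]
  if (sd(ta) == 0) return(list(ux = NA, uy = NA, valid = FALSE))
  best <- -Inf; bux <- NA; buy <- NA; bmag <- Inf
  for (dy in (predicted[2] - search):(predicted[2] + search)) {
    for (dx in (predicted[1] - search):(predicted[1] + search)) {
      ys2 <- ys + dy; xs2 <- xs + dx
      if (min(ys2) < 1 || min(xs2) < 1 ||
          max(ys2) > nrow(frame_b) || max(xs2) > ncol(frame_b))
        return(list(ux = NA, uy = NA, valid = FALSE))
      s <- cross_correlation_score(ta, frame_b[ys2, xs2], zero_mean = zero_mean)
      mag <- dy^2 + dx^2
      if (s > best || (s == best && mag < bmag)) {
        best <- s; bux <- dx; buy <- dy; bmag <- mag
      }
    }
  }
  list(ux = bux, uy = buy, valid = TRUE)
}

# brute-force verifier of the alternation + prominence conditions
check_extrema_conditions <- function(signal, ex) {
  mins <- ex$minima; maxs <- ex$maxima; delta <- ex$delta
  merged <- sort(c(mins, maxs))
  # strict alternation starting with a minimum
  if (length(merged) > 0) {
    kinds <- ifelse(merged %in% mins, "min", "max")
    if (kinds[1] != "min") return("does not start with a minimum")
    if (any(kinds[-1] == kinds[-length(kinds)])) return("not alternating")
  }
  for (k in seq_along(maxs)) {
    lo <- mins[k]
    hi <- if (k + 1 <= length(mins)) mins[k + 1] else length(signal)
    if (signal[maxs[k]] < max(signal[lo:hi])) return("max not absolute in interval")
    if (signal[maxs[k]] <= signal[lo] + delta - 1e-12) return("rise below delta")
  }
  for (k in seq_along(mins)) {
    lo <- if (k - 1 >= 1) maxs[k - 1] else 1
    hi <- if (k <= length(maxs)) maxs[k] else length(signal)
    if (signal[mins[k]] > min(signal[lo:hi])) return("min not absolute in interval")
    if (k - 1 >= 1 && signal[mins[k]] >= signal[maxs[k - 1]] - delta + 1e-12)
      return("drop below delta")
  }
  TRUE
}

# one-center synthetic beating scene used across modules
small_scene <- function(size = 128, r0 = 16, k = 0.01, peak = 5, bpm = 60,
                        fps = 10, noise_sd = 2, seed = 7, ...) {
  scene_spec(size = size,
             centers = list(list(position = c(size / 2, size / 2),
                                 params = sheet_params(c1 = 1, c2 = 1, k = k,
                                                       sigma_star = 1, r0 = r0),
                                 waveform = beat_waveform(period = 60 / bpm,
                                                          contraction_rise = 0.1,
                                                          relaxation_tau = 0.25),
                                 phase = 0, peak_displacement = peak)),
             texture_seed = seed, noise_sd = noise_sd, fps = fps, ...)
}
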