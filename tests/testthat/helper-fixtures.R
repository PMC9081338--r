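# Shared fixtures, built in code at test time.

noiseless_params <- function(...) kinetics_params(noise_sd_frac = 0, ...)

# a tiny image with well-separated bright discs on a flat background
disc_image <- function(centers, radius = 6, value = 100, shape = c(80, 120),
                       background = 0) {
  img <- matrix(background, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    for (r in max(1, r0 - radius):min(shape[1], r0 + radius))
      for (cc in max(1, c0 - radius):min(shape[2], c0 + radius))
        if ((r - r0)^2 + (cc - c0)^2 <= radius^2) img[r, cc] <- value
  }
  img
}

five_disc_centers <- rbind(c(15, 20), c(15, 60), c(15, 100),
                           c(60, 35), c(60, 85))

degenerate_mixture <- function(fate) {
  p <- as.numeric(fate == c("noncycling", "division", "binucleation",
                            "polyploidization"))
  fate_mixture(p[1], p[2], p[3], p[4], normalize = FALSE)
}

counts_of <- function(blue, red, yellow, green) {
  structure(list(n_blue = blue, n_red = red, n_yellow = yellow,
                 n_green = green), class = "state_counts")
}
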