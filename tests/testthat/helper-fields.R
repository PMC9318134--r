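# Shared fixtures: small synthetic fields keep the suite fast; the
# generator itself is first-class tested code.

make_field <- function(target = 15, extent = c(96, 96), seed = 1L, ...) {
  generate_field(field_gen_params(extent = extent, target_fraction = target,
                                  seed = seed, ...))
}

make_pair <- function(target = 15, extent = c(96, 96), seed = 1L,
                      noise_intensity = 0.5) {
  good <- make_field(target, extent, seed)
  list(good = good,
       noise = add_background_noise(good, noise_intensity, seed = seed + 1L))
}

# Independent per-pixel color-distance oracle (scalar loop, no vectorized
# selection code shared with the implementation).
brute_force_select <- function(img, colors, fuzziness, metric = "chebyshev") {
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      px <- img[i, j, ]
      dmin <- Inf
      for (k in seq_len(nrow(colors))) {
        dv <- abs(px - colors[k, ])
        d <- if (metric == "chebyshev") max(dv) else sqrt(sum(dv^2))
        dmin <- min(dmin, d)
      }
      out[i, j] <- as.numeric(dmin <= fuzziness)
    }
  }
  out
}
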