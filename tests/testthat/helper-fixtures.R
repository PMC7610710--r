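# Shared fixtures: tiny networks and cohorts built in code at test time.

# A small SFCN accepting 32^3 inputs, cheap enough for gradient and
# determinism checks.
tiny_sfcn_spec <- function(n_output = 10L, norm_kind = "batch",
                           dropout_rate = 0) {
  sfcn_spec(input_shape = c(32L, 32L, 32L),
            channel_widths = c(2L, 3L, 3L, 3L, 4L, 4L, n_output),
            n_output = n_output, dropout_rate = dropout_rate,
            norm_kind = norm_kind)
}

random_volume <- function(shape = c(32, 32, 32), seed = 1) {
  set.seed(seed)
  array(rnorm(prod(shape)), shape)
}

# Independent analytic parameter tally for the SFCN: per layer
# kernel_volume * C_in * C_out + C_out biases + 2 * C_out per affine norm.
# Written from the block structure alone, not from the network object.
sfcn_analytic_params <- function(widths = c(32, 64, 128, 256, 256, 64, 40)) {
  cin <- 1
  total <- 0
  for (b in 1:5) {
    total <- total + 27 * cin * widths[b] + widths[b] + 2 * widths[b]
    cin <- widths[b]
  }
  total <- total + 1 * cin * widths[6] + widths[6] + 2 * widths[6]
  total + widths[6] * widths[7] + widths[7]
}

# Independent tally for the 3D residual networks (convs bias-free, affine
# norms, 1x1x1 projection shortcuts, biased head).
resnet3d_analytic_params <- function(depth, n_in = 1, n_out = 40) {
  conv <- function(k, cin, cout) k^3 * cin * cout
  norm <- function(c) 2 * c
  widths <- c(64, 128, 256, 512)
  blocks <- switch(as.character(depth),
                   "18" = c(2, 2, 2, 2), "50" = c(3, 4, 6, 3),
                   "101" = c(3, 4, 23, 3), "152" = c(3, 8, 36, 3))
  bottleneck <- depth >= 50
  total <- conv(7, n_in, 64) + norm(64)
  cin <- 64
  for (s in 1:4) for (b in seq_len(blocks[s])) {
    w <- widths[s]
    down <- (b == 1) && (s > 1 || (bottleneck && cin != 4 * w))
    if (bottleneck) {
      total <- total + conv(1, cin, w) + norm(w) + conv(3, w, w) + norm(w) +
        conv(1, w, 4 * w) + norm(4 * w)
      if (down) total <- total + conv(1, cin, 4 * w) + norm(4 * w)
      cin <- 4 * w
    } else {
      total <- total + conv(3, cin, w) + norm(w) + conv(3, w, w) + norm(w)
      if (down) total <- total + conv(1, cin, w) + norm(w)
      cin <- w
    }
  }
  total + cin * n_out + n_out
}

# A small noisy cohort shared across the slower tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(phantom_config(n_subjects = 12, seed = 3,
                                               noise_sd = 0.02))
    cache
  }
})
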