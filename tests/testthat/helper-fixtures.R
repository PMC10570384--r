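# Shared builders for small synthetic fixtures. All randomness is seeded by
# the caller so tests stay deterministic.

noiseless_optical <- function(...) {
  optical_model(shot_noise_scale = 0, read_noise_sd = 0, ...)
}

# a small scene that renders in milliseconds
tiny_scene <- function(n_cells = 12, seed = 1, ...) {
  make_scene(n_cells = n_cells, dim = c(96L, 96L, 8L), seed = seed, ...)
}

# one-cell scene with fully controlled parameters, used for closed-form checks
single_cell_scene <- function(base_green = 100, activity = 0.5,
                              hemisphere = "L") {
  sc <- make_scene(n_cells = 1, dim = c(64L, 64L, 6L), seed = 1,
                   hemisphere = hemisphere)
  sc$cells$x <- 32; sc$cells$y <- 32; sc$cells$z <- 9
  sc$cells$base_green <- base_green
  sc$cells$activity <- activity
  sc
}

# per-cell mean table extracted with the ground-truth mask
extract_truth_means <- function(stack) {
  tbl <- extract_cell_fluorescence(stack$mask, stack$green, stack$red)
  tbl[match(stack$cells$cell_id, tbl$cell_id), ]
}

# brute-force slab averaging oracle: explicit slicing + mean
slab_oracle <- function(stack, group_size, skip, z_step = 3) {
  nz <- dim(stack)[3]
  starts <- seq(1, nz, by = group_size + skip)
  starts <- starts[starts + group_size - 1 <= nz]
  slabs <- lapply(starts, function(s) {
    acc <- stack[, , s]
    if (group_size > 1)
      for (k in (s + 1):(s + group_size - 1)) acc <- acc + stack[, , k]
    acc / group_size
  })
  depth <- vapply(starts,
                  function(s) mean((s:(s + group_size - 1) - 1) * z_step),
                  numeric(1))
  list(slabs = slabs, depth = depth)
}

# direct d-prime formula on sums, independent of the package implementation
dprime_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  (ma - mb) / sqrt(0.5 * (va + vb))
}
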