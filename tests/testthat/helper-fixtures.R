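# Shared fixtures, built in code at test time.

# Small noise-free phantom movie plus its mask/probe geometry.
make_phantom_movie <- function(class = "global", noise = "none", seed = 1,
                               n_frames = 30, ...) {
  cell <- cell_phantom()
  resp <- response_model(class, ...)
  acq <- acquisition_model(noise = noise)
  stack <- generate_fret_movie(cell, resp, acq, n_frames = n_frames,
                               seed = seed)
  list(cell = cell, stack = stack, resp = resp, acq = acq)
}

# Constant-intensity stack: donor = d, acceptor = a everywhere.
make_flat_stack <- function(d = 100, a = 200, dim_hw = c(20, 20),
                            n_frames = 6, stimulus_frame = 4,
                            pixel_size = 1, frame_interval = 1) {
  channel_stack(array(d, c(dim_hw, n_frames)),
                array(a, c(dim_hw, n_frames)),
                pixel_size, frame_interval, stimulus_frame)
}

# Rectangular band mask (rows r1..r2, all columns).
make_band_mask <- function(dim_hw, rows) {
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  m[rows, ] <- TRUE
  m
}

# Match tracked beads to ground truth by nearest reference position and
# return the per-bead displacement errors (um).
bead_errors <- function(tracked, truth) {
  vapply(seq_len(nrow(tracked)), function(i) {
    j <- which.min((truth$x_um - tracked$x_um[i])^2 +
                     (truth$y_um - tracked$y_um[i])^2)
    sqrt((tracked$ux_um[i] - truth$ux_um[j])^2 +
           (tracked$uy_um[i] - truth$uy_um[j])^2)
  }, numeric(1))
}

# Brute-force Freeman-Halton oracle: enumerate every non-negative integer
# table cell-by-cell (no margin-aware recursion), keep those with the
# observed margins, and sum the probabilities (computed from factorials
# via prod(choose())) of tables no more probable than the observed one.
fisher_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  cells <- expand.grid(rep(list(0:max(rs)), length(m)))
  keep <- rep(TRUE, nrow(cells))
  tab_prob <- function(v) {
    tb <- matrix(v, nrow(m), ncol(m))
    if (!all(rowSums(tb) == rs) || !all(colSums(tb) == cs)) return(NA_real_)
    # multivariate hypergeometric: prod over columns of multinomials
    num <- prod(vapply(seq_len(ncol(tb)), function(j) {
      f <- factorial(cs[j]) / prod(factorial(tb[, j]))
      f
    }, numeric(1)))
    den <- factorial(N) / prod(factorial(rs))
    num / den
  }
  probs <- apply(cells, 1, tab_prob)
  probs <- probs[!is.na(probs)]
  p_obs <- tab_prob(as.vector(m))
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}
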