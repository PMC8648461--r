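# Shared fixture builders: everything is generated in code at test time.

# Tiny elastogram with hand-placed colors: a 32x32 frame whose ROI ellipse is
# filled with an exact pixel recipe, bypassing the generator.
manual_elastogram <- function(recipe = c(blue = 0.5, green = 0.5,
                                         red = 0, other = 0)) {
  h <- w <- 32L
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  row_i <- matrix(seq_len(h), h, w)
  col_i <- matrix(seq_len(w), h, w, byrow = TRUE)
  roi <- ((row_i - cy) / (0.4 * h))^2 + ((col_i - cx) / (0.4 * w))^2 <= 1
  idx <- which(roi)
  n <- length(idx)
  counts <- floor(recipe * n)
  counts[1] <- counts[1] + n - sum(counts)
  pal <- elasto_palette()
  lab <- rep.int(1:4, counts)
  px <- array(10, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[idx] <- pal[lab, ch]
    px[, , ch] <- plane
  }
  elastogram(px, roi)
}

# Scalar-loop LSTM cell: the independent oracle for cell_step. Every product
# is an explicit element-by-element accumulation; no matrix ops.
scalar_cell_step <- function(params, x, h_prev, C_prev) {
  m <- params$m; d <- params$d
  lin <- function(Wx, Wh, b, j) {
    acc <- b[j]
    for (k in seq_len(d)) acc <- acc + Wx[j, k] * x[k]
    for (k in seq_len(m)) acc <- acc + Wh[j, k] * h_prev[k]
    acc
  }
  f <- i <- g <- o <- C <- hh <- numeric(m)
  for (j in seq_len(m)) {
    f[j] <- 1 / (1 + exp(-lin(params$W_fx, params$W_fh, params$b_f, j)))
    i[j] <- 1 / (1 + exp(-lin(params$W_ix, params$W_ih, params$b_i, j)))
    g[j] <- tanh(lin(params$W_cx, params$W_ch, params$b_c, j))
    o[j] <- 1 / (1 + exp(-lin(params$W_ox, params$W_oh, params$b_o, j)))
    C[j] <- f[j] * C_prev[j] + i[j] * g[j]
    hh[j] <- o[j] * tanh(C[j])
  }
  list(h = hh, C = C, f = f, i = i, o = o, C_cand = g)
}

random_params <- function(d, m, seed) {
  p <- lstm_params(d, m, rng_seed = seed)
  # scatter biases too so the oracle exercises every term
  set.seed(seed + 7)
  p$b_f <- rnorm(m); p$b_i <- rnorm(m); p$b_c <- rnorm(m); p$b_o <- rnorm(m)
  p
}
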