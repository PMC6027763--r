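# shared fixture builders; everything is generated in code, no stored data

const_channel <- function(value, n = 32, role = "signal",
                          pixel_size_um = 0.5) {
  channel_image(matrix(value, n, n), role = role,
                pixel_size_um = pixel_size_um)
}

mat_channel <- function(m, role = "signal", pixel_size_um = 0.5) {
  channel_image(m, role = role, pixel_size_um = pixel_size_um)
}

# disc of given radius (px) centred in an n x n zero matrix
disc_matrix <- function(n, r, value = 1, cy = (n + 1) / 2,
                        cx = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  m <- matrix(0, n, n)
  m[d2 <= r^2] <- value
  m
}

# direct-convolution Gaussian lowpass oracle with the same truncated,
# renormalized boundary rule as the implementation (O(n^2 k^2), tiny
# images only)
brute_lowpass <- function(m, sigma_px) {
  n_r <- nrow(m); n_c <- ncol(m)
  wr <- outer(seq_len(n_r), seq_len(n_r),
              function(i, j) exp(-(i - j)^2 / (2 * sigma_px^2)))
  wr <- wr / rowSums(wr)
  wc <- outer(seq_len(n_c), seq_len(n_c),
              function(i, j) exp(-(i - j)^2 / (2 * sigma_px^2)))
  wc <- wc / rowSums(wc)
  out <- matrix(0, n_r, n_c)
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    out[i, j] <- sum(outer(wr[i, ], wc[j, ]) * m)
  }
  out
}

# small quick section parameters used across tests
quick_params <- function(n = 256L, ...) {
  section_sim_params(image_size_px = c(n, n), ...)
}

# classical two-way sums-of-squares decomposition computed from scratch
# (balanced designs), independent of aov
brute_two_way_ss <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  N <- length(y); gm <- mean(y)
  a_means <- tapply(y, A, mean); b_means <- tapply(y, B, mean)
  cell_means <- tapply(y, list(A, B), mean)
  n_a <- tapply(y, A, length); n_b <- tapply(y, B, length)
  n_cell <- table(A, B)
  ss_a <- sum(n_a * (a_means - gm)^2)
  ss_b <- sum(n_b * (b_means - gm)^2)
  ss_cells <- sum(n_cell * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_cells
  df_a <- nlevels(A) - 1L; df_b <- nlevels(B) - 1L
  df_ab <- df_a * df_b
  df_res <- N - nlevels(A) * nlevels(B)
  list(ss = c(ss_a, ss_b, ss_ab, ss_res), df = c(df_a, df_b, df_ab, df_res),
       F = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_res / df_res),
       ss_total = ss_tot)
}

# random balanced two-cell-replicated factorial table
random_balanced_table <- function(n_a = 3, n_b = 4, n_rep = 3) {
  A <- rep(paste0("a", seq_len(n_a)), each = n_b * n_rep)
  B <- rep(rep(paste0("b", seq_len(n_b)), each = n_rep), times = n_a)
  data.frame(braak_group = A, region = B,
             ir_area_percent = rnorm(length(A), rep(runif(n_a, 0, 5),
                                                    each = n_b * n_rep)))
}
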