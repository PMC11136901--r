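# independent Boyce oracle: literal P/E construction + rank correlation
boyce_oracle <- function(pres, bg, window_frac = 0.1, res = 100) {
  r <- range(bg)
  w <- window_frac * diff(r)
  centers <- seq(r[1], r[2], length.out = res)
  P <- E <- numeric(res)
  for (i in seq_len(res)) {
    lo <- centers[i] - w / 2; hi <- centers[i] + w / 2
    P[i] <- sum(pres >= lo & pres <= hi) / length(pres)
    E[i] <- sum(bg >= lo & bg <= hi) / length(bg)
  }
  keep <- E > 0
  pe <- P[keep] / E[keep]
  cc <- centers[keep]
  # Spearman as Pearson on ranks
  stats::cor(rank(pe), rank(cc))
}

# tiny binary-map builder on a shared 4 x 5 grid
bm <- function(ones, nr = 4, nc = 5) {
  cells <- matrix(0, nr, nc)
  cells[ones] <- 1
  structure(list(cells = cells, threshold = 0.5, omission = 0.1,
                 lon = seq(100.5, by = 1, length.out = nc),
                 lat = seq(30.5, by = 1, length.out = nr), meta = list()),
            class = "binary_map")
}
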