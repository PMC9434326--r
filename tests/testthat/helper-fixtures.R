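# Shared fixtures: the dense circadian design (0-48 h every 2 h, 3 reps)
# and independent brute-force oracles used across tests.

std_times <- function(reps = 3) rep(seq(0, 48, by = 2), each = reps)

std_cols <- function(reps = 3) {
  paste0(rep(seq(0, 48, by = 2), each = reps),
         ".", rep(seq_len(reps), 25))
}

# wrap a values matrix (features x samples) as the wide tibble dialect
make_wide <- function(vals, ids = sprintf("f%02d", seq_len(nrow(vals))),
                      cols = std_cols()) {
  colnames(vals) <- cols
  dplyr::bind_cols(tibble::tibble(feature_id = ids),
                   tibble::as_tibble(vals))
}

wide_from_series <- function(..., cols = std_cols()) {
  series <- list(...)
  make_wide(do.call(rbind, series),
            ids = sprintf("f%02d", seq_along(series)), cols = cols)
}

# brute-force step-up Benjamini-Hochberg, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  q[ord] <- pmin(adj, 1)
  q
}

# exact two-sided Fisher p by full hypergeometric enumeration over all
# tables with the observed margins
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
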