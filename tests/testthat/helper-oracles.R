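# Independent brute-force oracles used across the suite. These stay
# loop-based and deliberately share no code with the package internals.

# Term-by-term moment-distance summation over samples inside [lp, rp].
md_loop_oracle <- function(rho, x, lp = x[1], rp = x[length(x)]) {
  md_lp <- 0
  md_rp <- 0
  for (i in seq_along(rho)) {
    if (x[i] >= lp && x[i] <= rp) {
      md_lp <- md_lp + sqrt(rho[i]^2 + (x[i] - lp)^2)
      md_rp <- md_rp + sqrt(rho[i]^2 + (rp - x[i])^2)
    }
  }
  list(md_lp = md_lp, md_rp = md_rp, mdi = md_rp - md_lp,
       mdin = (md_rp - md_lp) / (md_rp + md_lp),
       mdrlr = md_lp / md_rp, mdrrl = md_rp / md_lp)
}

# Symmetric-reflection index (0-based), matching np.pad mode "symmetric".
reflect_oracle <- function(i, n) {
  if (n == 1) return(0)
  p <- 2 * n
  i <- i %% p
  if (i < 0) i <- i + p
  if (i < n) i else p - 1 - i
}

# Brute-force co-occurrence features at one pixel of a quantized image
# (0-based levels), enumerating all window cells and the four standard
# direction offsets, symmetrized.
glcm_pixel_oracle <- function(q, r, c, levels, window, dist) {
  h <- window %/% 2
  nr <- nrow(q); nc <- ncol(q)
  P <- matrix(0, levels, levels)
  offs <- list(c(0, dist), c(-dist, dist), c(-dist, 0), c(-dist, -dist))
  for (wr in (r - h):(r + h)) {
    for (wc in (c - h):(c + h)) {
      a <- q[reflect_oracle(wr - 1, nr) + 1, reflect_oracle(wc - 1, nc) + 1]
      for (o in offs) {
        b <- q[reflect_oracle(wr - 1 + o[1], nr) + 1,
               reflect_oracle(wc - 1 + o[2], nc) + 1]
        P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
        P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
      }
    }
  }
  P <- P / sum(P)
  lev <- 0:(levels - 1)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  var_i <- sum((lev - mu_i)^2 * pi_); var_j <- sum((lev - mu_j)^2 * pj_)
  con <- 0; asm <- 0; ent <- 0; cov <- 0
  for (i in seq_len(levels)) {
    for (j in seq_len(levels)) {
      p <- P[i, j]
      if (p > 0) {
        con <- con + (i - j)^2 * p
        asm <- asm + p^2
        ent <- ent - p * log(p)
        cov <- cov + (lev[i] - mu_i) * (lev[j] - mu_j) * p
      }
    }
  }
  list(VAR = var_i, ENT = ent,
       COR = if (var_i > 0 && var_j > 0) cov / sqrt(var_i * var_j) else NaN,
       CON = con, ASM = asm, P = P)
}

# Group-by-label means, excluding non-finite values.
group_mean_oracle <- function(values, labels, n_groups) {
  out <- rep(NaN, n_groups)
  for (g in seq_len(n_groups)) {
    v <- values[labels == g]
    v <- v[is.finite(v)]
    if (length(v)) out[g] <- sum(v) / length(v)
  }
  out
}

# Counting-based accuracy statistics.
accuracy_oracle <- function(truth, pred) {
  lev <- sort(unique(c(truth, pred)))
  C <- length(lev)
  cm <- matrix(0, C, C)
  for (i in seq_along(truth)) {
    cm[match(truth[i], lev), match(pred[i], lev)] <-
      cm[match(truth[i], lev), match(pred[i], lev)] + 1
  }
  total <- sum(cm)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  list(oa = 100 * p_o, kappa = (p_o - p_e) / (1 - p_e),
       pa = 100 * diag(cm) / rowSums(cm),
       ua = 100 * diag(cm) / colSums(cm), cm = cm)
}

# Small random cube fixture with known wavelengths.
random_cube <- function(bands = 12, rows = 4, cols = 5,
                        range_nm = c(400, 1700), seed = 1) {
  withr::with_seed(seed, {
    hyper_cube(array(runif(bands * rows * cols), c(bands, rows, cols)),
               seq(range_nm[1], range_nm[2], length.out = bands))
  })
}
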