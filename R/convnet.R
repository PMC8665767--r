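# Minimal 1-D convolutional network for TSS classification, written in
# plain R. Input: 21 positions x 2 channels (sense, antisense z-scored
# counts). Architecture: conv (valid padding) -> ReLU -> max-pool ->
# dropout -> dense -> sigmoid, trained with Adam on cross-entropy with
# early stopping on validation loss.

# Patch matrix for the convolution: each sample row becomes n_pos rows of
# kernel*2 values, so the conv layer is a single matrix product.
conv_patches <- function(X, kernel) {
  n <- nrow(X)
  n_bins <- ncol(X) / 2
  n_pos <- n_bins - kernel + 1
  P <- matrix(0, n * n_pos, kernel * 2)
  for (t in seq_len(n_pos)) {
    idx <- seq(t, n * n_pos, by = n_pos)
    P[idx, seq_len(kernel)] <- X[, t:(t + kernel - 1), drop = FALSE]
    P[idx, kernel + seq_len(kernel)] <-
      X[, n_bins + (t:(t + kernel - 1)), drop = FALSE]
  }
  P
}

conv_forward <- function(fit, X, drop_mask = NULL) {
  n <- nrow(X)
  k <- fit$kernel; F <- fit$filters; pool <- fit$pool
  n_pos <- ncol(X) / 2 - k + 1
  n_pool <- n_pos %/% pool
  P <- conv_patches(X, k)                       # (n*n_pos) x 2k
  Z1 <- sweep(P %*% fit$W1, 2, fit$b1, `+`)     # (n*n_pos) x F
  A1 <- pmax(Z1, 0)
  H <- matrix(0, n, n_pool * F)
  amax <- matrix(0L, n, n_pool * F)             # argmax row in Z1
  for (s in seq_len(n)) {
    rows <- (s - 1) * n_pos + seq_len(n_pos)
    for (q in seq_len(n_pool)) {
      seg <- rows[((q - 1) * pool + 1):(q * pool)]
      w <- A1[seg, , drop = FALSE]
      top <- max.col(t(w), ties.method = "first")
      cols <- (q - 1) * F + seq_len(F)
      H[s, cols] <- w[cbind(top, seq_len(F))]
      amax[s, cols] <- seg[top]
    }
  }
  if (!is.null(drop_mask)) H <- H * drop_mask
  eta <- drop(H %*% fit$w2) + fit$b2
  eta <- pmin(pmax(eta, -30), 30)
  list(p = 1 / (1 + exp(-eta)), H = H, amax = amax, P = P, Z1 = Z1)
}

fit_conv_tss <- function(X, y, seed = 1L, filters = 16, kernel = 5,
                         pool = 2, dropout = 0.3, lr = 1e-3,
                         epochs = 200, patience = 15, batch = 32,
                         val_frac = 0.2) {
  set.seed(seed)
  n <- nrow(X)
  n_pos <- ncol(X) / 2 - kernel + 1
  n_pool <- n_pos %/% pool
  n_hidden <- n_pool * filters
  fit <- list(kernel = kernel, filters = filters, pool = pool,
              W1 = matrix(stats::rnorm(2 * kernel * filters, 0, 0.2),
                          2 * kernel, filters),
              b1 = numeric(filters),
              w2 = stats::rnorm(n_hidden, 0, 0.1),
              b2 = 0)
  val <- sample(n, max(2, round(val_frac * n)))
  tr <- setdiff(seq_len(n), val)
  adam <- list(m = lapply(fit[c("W1", "b1", "w2", "b2")],
                          function(p) p * 0),
               v = lapply(fit[c("W1", "b1", "w2", "b2")],
                          function(p) p * 0),
               t = 0)
  bce <- function(p, y) -mean(y * log(p + 1e-12) +
                                (1 - y) * log(1 - p + 1e-12))
  best <- list(loss = Inf, fit = fit, bad = 0)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    for (start in seq(1, length(ord), by = batch)) {
      idx <- ord[start:min(start + batch - 1, length(ord))]
      nb <- length(idx)
      mask <- matrix(stats::rbinom(nb * n_hidden, 1, 1 - dropout),
                     nb, n_hidden) / (1 - dropout)
      fw <- conv_forward(fit, X[idx, , drop = FALSE], drop_mask = mask)
      d_eta <- (fw$p - y[idx]) / nb
      g <- list(
        w2 = drop(crossprod(fw$H, d_eta)),
        b2 = sum(d_eta))
      dH <- outer(d_eta, fit$w2) * mask
      dZ1 <- matrix(0, nrow(fw$Z1), fit$filters)
      for (s in seq_len(nb)) {
        for (col in which(dH[s, ] != 0)) {
          f <- (col - 1) %% fit$filters + 1
          r <- fw$amax[s, col]  # global row index into Z1 (see forward)
          if (fw$Z1[r, f] > 0) dZ1[r, f] <- dZ1[r, f] + dH[s, col]
        }
      }
      g$W1 <- crossprod(fw$P, dZ1)
      g$b1 <- colSums(dZ1)
      adam$t <- adam$t + 1
      for (nm in names(g)) {
        adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g[[nm]]
        adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g[[nm]]^2
        mh <- adam$m[[nm]] / (1 - 0.9^adam$t)
        vh <- adam$v[[nm]] / (1 - 0.999^adam$t)
        fit[[nm]] <- fit[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
    vloss <- bce(conv_forward(fit, X[val, , drop = FALSE])$p, y[val])
    if (vloss < best$loss - 1e-5) {
      best$loss <- vloss
      best$fit <- fit
      best$bad <- 0
    } else {
      best$bad <- best$bad + 1
      if (best$bad >= patience) break
    }
  }
  best$fit
}

predict_conv_tss <- function(fit, X) {
  conv_forward(fit, X)$p
}
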