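# Small convolutional network for m x m single-channel images:
#   conv 3x3 (16 filters, valid) -> ReLU -> maxpool 2x2
#   conv 3x3 (32 filters, valid) -> ReLU -> maxpool 2x2
#   dense 64 -> ReLU -> dense 1 -> sigmoid
# Binary cross-entropy loss, Adam (lr 1e-3), up to `epochs` epochs with
# early stopping on a validation split. Pooling is skipped when a spatial
# dimension is < 2, so the same architecture runs on small test images.
# Implemented with im2col so all convolutions are single matrix products.

# im2col: activations (N, H, W, C) -> patches (N * oH * oW, 9 * C) for a
# 3x3 valid convolution, plus the output spatial size.
conv_patches <- function(A) {
  d <- dim(A); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oH <- H - 2; oW <- W - 2
  P <- array(0, c(N, oH, oW, 9 * C))
  off <- 0
  for (dy in 0:2) for (dx in 0:2) {
    P[, , , off + seq_len(C)] <-
      A[, dy + seq_len(oH), dx + seq_len(oW), , drop = FALSE]
    off <- off + C
  }
  list(P = matrix(P, N * oH * oW, 9 * C), oH = oH, oW = oW)
}

# Scatter-add of patch gradients back onto the input tensor.
conv_patches_backward <- function(dP, dims) {
  N <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]
  oH <- H - 2; oW <- W - 2
  dP <- array(dP, c(N, oH, oW, 9 * C))
  dA <- array(0, dims)
  off <- 0
  for (dy in 0:2) for (dx in 0:2) {
    dA[, dy + seq_len(oH), dx + seq_len(oW), ] <-
      dA[, dy + seq_len(oH), dx + seq_len(oW), , drop = FALSE] +
      dP[, , , off + seq_len(C), drop = FALSE]
    off <- off + C
  }
  dA
}

conv_forward <- function(A, K, b) {
  cp <- conv_patches(A)
  Z <- sweep(cp$P %*% K, 2, b, "+")
  list(Z = array(Z, c(dim(A)[1], cp$oH, cp$oW, ncol(K))), P = cp$P)
}

# 2x2 max pooling, stride 2; odd trailing row/column cropped.
pool_forward <- function(A) {
  d <- dim(A)
  if (d[2] < 2 || d[3] < 2) return(list(Z = A, skip = TRUE))
  oH <- d[2] %/% 2; oW <- d[3] %/% 2
  i1 <- 2 * seq_len(oH) - 1; j1 <- 2 * seq_len(oW) - 1
  s <- list(A[, i1, j1, , drop = FALSE], A[, i1 + 1, j1, , drop = FALSE],
            A[, i1, j1 + 1, , drop = FALSE], A[, i1 + 1, j1 + 1, , drop = FALSE])
  Z <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  arg <- (s[[1]] >= Z) * 1
  arg[arg == 0 & s[[2]] >= Z] <- 2
  arg[arg == 0 & s[[3]] >= Z] <- 3
  arg[arg == 0 & s[[4]] >= Z] <- 4
  list(Z = Z, arg = arg, skip = FALSE, in_dim = d)
}

pool_backward <- function(dZ, cache) {
  if (cache$skip) return(dZ)
  d <- cache$in_dim
  oH <- dim(dZ)[2]; oW <- dim(dZ)[3]
  i1 <- 2 * seq_len(oH) - 1; j1 <- 2 * seq_len(oW) - 1
  dA <- array(0, d)
  dA[, i1, j1, ] <- dZ * (cache$arg == 1)
  dA[, i1 + 1, j1, ] <- dZ * (cache$arg == 2)
  dA[, i1, j1 + 1, ] <- dZ * (cache$arg == 3)
  dA[, i1 + 1, j1 + 1, ] <- dZ * (cache$arg == 4)
  dA
}

cnn_init <- function(m, f1 = 16, f2 = 32, dense = 64) {
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  # trace the spatial dims to size the dense layer
  h <- m - 2; h <- if (h >= 2) h %/% 2 else h
  h <- h - 2; h <- if (h >= 2) h %/% 2 else h
  if (h < 1) stop("image side too small for the CNN architecture")
  list(K1 = he(9, f1, 9), b1 = numeric(f1),
       K2 = he(9 * f1, f2, 9 * f1), b2 = numeric(f2),
       W3 = he(h * h * f2, dense, h * h * f2), b3 = numeric(dense),
       W4 = he(dense, 1, dense), b4 = 0)
}

cnn_forward <- function(par, X) {
  N <- dim(X)[1]
  A0 <- array(X, c(dim(X), 1))
  c1 <- conv_forward(A0, par$K1, par$b1)
  R1 <- pmax(c1$Z, 0)
  p1 <- pool_forward(R1)
  c2 <- conv_forward(p1$Z, par$K2, par$b2)
  R2 <- pmax(c2$Z, 0)
  p2 <- pool_forward(R2)
  Fl <- matrix(p2$Z, N, prod(dim(p2$Z)[-1]))
  Z3 <- sweep(Fl %*% par$W3, 2, par$b3, "+")
  R3 <- pmax(Z3, 0)
  z4 <- as.vector(R3 %*% par$W4) + par$b4
  prob <- stats::plogis(z4)
  list(prob = prob, A0 = A0, c1 = c1, R1 = R1, p1 = p1, c2 = c2, R2 = R2,
       p2 = p2, Fl = Fl, R3 = R3)
}

cnn_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_cnn <- function(X, y, seed = 1, epochs = 100, batch_size = 8,
                    lr = 1e-3, patience = 15, val_fraction = 0.15) {
  m <- dim(X)[2]
  with_seed(seed + 31L, {
    par <- cnn_init(m)
    n <- length(y)
    n_val <- max(2, round(val_fraction * n))
    val_idx <- c(sample(which(y == 1), max(1, round(n_val / 2))),
                 sample(which(y == 0), max(1, round(n_val / 2))))
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , , drop = FALSE]; yval <- y[val_idx]
    mom <- lapply(par, function(p) p * 0)
    vel <- lapply(par, function(p) p * 0)
    t_step <- 0
    best <- list(loss = Inf, par = par); wait <- 0
    for (epoch in seq_len(epochs)) {
      ord <- sample(length(ytr))
      for (start in seq(1, length(ytr), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ytr))]
        fw <- cnn_forward(par, Xtr[bi, , , drop = FALSE])
        gr <- cnn_gradients(par, fw, ytr[bi])
        t_step <- t_step + 1
        for (nm in names(par)) {
          mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * gr[[nm]]
          vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * gr[[nm]]^2
          mhat <- mom[[nm]] / (1 - 0.9^t_step)
          vhat <- vel[[nm]] / (1 - 0.999^t_step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      val_loss <- cnn_loss(cnn_forward(par, Xval)$prob, yval)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, par = par); wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
    list(fit = "cnn", par = best$par, m = m, val_loss = best$loss)
  })
}

# Full gradient of the mean BCE loss w.r.t. all parameters.
cnn_gradients <- function(par, fw, y) {
  N <- length(y)
  dz4 <- (fw$prob - y) / N
  dW4 <- t(fw$R3) %*% dz4; db4 <- sum(dz4)
  dR3 <- outer(dz4, as.vector(par$W4))
  dZ3 <- dR3 * (fw$R3 > 0)
  dW3 <- t(fw$Fl) %*% dZ3; db3 <- colSums(dZ3)
  dFl <- dZ3 %*% t(par$W3)
  dP2 <- array(dFl, dim(fw$p2$Z))
  dR2 <- pool_backward(dP2, fw$p2)
  dZ2 <- dR2 * (fw$c2$Z > 0)
  d2 <- dim(fw$c2$Z)
  dZ2m <- matrix(dZ2, prod(d2[1:3]), d2[4])
  dK2 <- t(fw$c2$P) %*% dZ2m; db2 <- colSums(dZ2m)
  dP1 <- conv_patches_backward(dZ2m %*% t(par$K2), dim(fw$p1$Z))
  dR1 <- pool_backward(dP1, fw$p1)
  dZ1 <- dR1 * (fw$c1$Z > 0)
  d1 <- dim(dZ1)
  dZ1m <- matrix(dZ1, prod(d1[1:3]), d1[4])
  dK1 <- t(fw$c1$P) %*% dZ1m; db1 <- colSums(dZ1m)
  list(K1 = dK1, b1 = db1, K2 = dK2, b2 = db2, W3 = dW3, b3 = db3,
       W4 = dW4, b4 = db4)
}

predict_cnn <- function(model, X) {
  cnn_forward(model$par, X)$prob
}
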