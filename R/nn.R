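# Neural-network primitives for the interaction classifier.
#
# The whole model is expressed as plain matrix algebra so that the backward
# pass can be written (and verified against numerical differentiation)
# explicitly. Parameters live in a flat named list of matrices/vectors.

# He (Kaiming) normal initialization: variance 2/fan_in suits the ReLU
# activations used throughout
he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize model parameters
#'
#' He-normal weights, zero biases. Draws from the current RNG state;
#' callers seed beforehand for reproducibility.
#'
#' @param d embedding size
#' @param n_compartments localization vector length
#' @param edge_dim edge feature dimension (13: coabundance, colocalization,
#'   11 technique counts)
#' @return named list of parameter matrices/vectors
#' @keywords internal
init_params <- function(d, n_compartments, edge_dim = 2 + N_TECHNIQUES) {
  h2 <- max(1L, d %/% 2L)
  list(
    # per-feature projection blocks (2 FC layers each)
    pe_W1 = he_init(2, d), pe_b1 = numeric(d),
    pe_W2 = he_init(d, d), pe_b2 = numeric(d),
    pa_W1 = he_init(2, d), pa_b1 = numeric(d),
    pa_W2 = he_init(d, d), pa_b2 = numeric(d),
    pl_W1 = he_init(n_compartments, d), pl_b1 = numeric(d),
    pl_W2 = he_init(d, d), pl_b2 = numeric(d),
    # graph attention layer (single head)
    gat_W = he_init(d, d), gat_asrc = runif(d, -0.1, 0.1),
    gat_adst = runif(d, -0.1, 0.1), gat_b = numeric(d),
    # deep set: phi (1 FC), rho (2 FC)
    phi_W = he_init(d, d), phi_b = numeric(d),
    rho_W1 = he_init(d, d), rho_b1 = numeric(d),
    rho_W2 = he_init(d, d), rho_b2 = numeric(d),
    # classification head (3 FC layers -> sigmoid)
    hd_W1 = he_init(d + edge_dim, d), hd_b1 = numeric(d),
    hd_W2 = he_init(d, h2), hd_b2 = numeric(h2),
    hd_W3 = he_init(h2, 1), hd_b3 = numeric(1)
  )
}

# Message-passing structure: directed copies of each undirected edge plus
# one self-loop per node, with the permutation-free bookkeeping the GAT
# softmax needs. `edge_index` rows index into 1..n.
build_graph <- function(edge_index, n) {
  src <- c(edge_index[, 1], edge_index[, 2], seq_len(n))
  dst <- c(edge_index[, 2], edge_index[, 1], seq_len(n))
  # canonical (dst, src) order: attention sums then accumulate in the same
  # order regardless of how the input edges were oriented or sorted
  ord <- order(dst, src)
  list(src = src[ord], dst = dst[ord], n = n)
}

segment_max <- function(x, group, n) {
  out <- tapply(x, group, max)
  v <- rep(-Inf, n)
  v[as.integer(names(out))] <- out
  v
}

# group-sum of a matrix into n rows (groups may not cover 1..n)
scatter_sum <- function(x, idx, n) {
  agg <- rowsum(x, idx)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# M + bias row-vector, avoiding sweep()'s aperm overhead
add_bias <- function(M, b) M + rep(b, each = nrow(M))

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# two-layer feed-forward block: relu after layer 1, dropout, linear layer 2
ff2_forward <- function(X, W1, b1, W2, b2, p, training) {
  A1 <- add_bias(X %*% W1, b1)
  H <- relu(A1)
  mask <- if (training) dropout_mask(nrow(H), ncol(H), p) else NULL
  Hd <- apply_mask(H, mask)
  out <- add_bias(Hd %*% W2, b2)
  list(out = out, X = X, A1 = A1, Hd = Hd, mask = mask)
}

ff2_backward <- function(cache, dOut, W1, W2) {
  dW2 <- crossprod(cache$Hd, dOut)
  db2 <- colSums(dOut)
  dHd <- dOut %*% t(W2)
  dH <- apply_mask(dHd, cache$mask)
  dA1 <- dH * (cache$A1 > 0)
  dW1 <- crossprod(cache$X, dA1)
  db1 <- colSums(dA1)
  dX <- dA1 %*% t(W1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dX = dX)
}

#' Full forward pass of the interaction classifier
#'
#' Node stage: each feature block (expression+missing flag,
#' abundance+missing flag, localization vector) is projected into the joint
#' embedding space by its own 2-layer block; the three projections are
#' summed and passed through one graph-attention layer over the
#' message-passing graph (attention coefficients via leaky-ReLU scoring and
#' per-target softmax, self-loops included). Edge stage: both endpoint
#' embeddings go through phi (1 FC layer), are summed (order-invariant) and
#' passed through rho (2 FC layers); the result is concatenated with the
#' edge features and scored by a 3-layer head with terminal sigmoid.
#'
#' @param params parameter list from \code{init_params}
#' @param nf node feature list (expression, abundance, localization)
#' @param graph from \code{build_graph}
#' @param batch_idx integer matrix (B x 2) of queried endpoint rows
#' @param edge_feat numeric matrix (B x edge_dim)
#' @param dropout dropout probability (training only)
#' @param training logical; enables dropout
#' @return list(prob, logit, cache)
#' @keywords internal
nn_forward <- function(params, nf, graph, batch_idx, edge_feat,
                       dropout = 0, training = FALSE) {
  P <- params
  ce <- ff2_forward(nf$expression, P$pe_W1, P$pe_b1, P$pe_W2, P$pe_b2,
                    dropout, training)
  ca <- ff2_forward(nf$abundance, P$pa_W1, P$pa_b1, P$pa_W2, P$pa_b2,
                    dropout, training)
  cl <- ff2_forward(nf$localization, P$pl_W1, P$pl_b1, P$pl_W2, P$pl_b2,
                    dropout, training)
  Z <- ce$out + ca$out + cl$out
  n <- nrow(Z)

  # graph attention
  ZW <- Z %*% P$gat_W
  ssrc <- drop(ZW %*% P$gat_asrc)
  sdst <- drop(ZW %*% P$gat_adst)
  pre_raw <- ssrc[graph$src] + sdst[graph$dst]
  pre <- ifelse(pre_raw > 0, pre_raw, 0.2 * pre_raw)
  mx <- segment_max(pre, graph$dst, n)
  ex <- exp(pre - mx[graph$dst])
  denom <- drop(scatter_sum(cbind(ex), graph$dst, n))
  alpha <- ex / denom[graph$dst]
  M <- scatter_sum(alpha * ZW[graph$src, , drop = FALSE], graph$dst, n)
  # residual connection keeps per-protein information that neighborhood
  # aggregation would otherwise smooth away
  Mb <- add_bias(M, P$gat_b) + Z
  E <- relu(Mb)

  # deep set over endpoint embeddings
  u <- batch_idx[, 1]; v <- batch_idx[, 2]
  Au <- add_bias(E[u, , drop = FALSE] %*% P$phi_W, P$phi_b)
  Av <- add_bias(E[v, , drop = FALSE] %*% P$phi_W, P$phi_b)
  S <- relu(Au) + relu(Av)
  cr <- ff2_forward(S, P$rho_W1, P$rho_b1, P$rho_W2, P$rho_b2,
                    dropout, training)

  # head
  Hcat <- cbind(cr$out, edge_feat)
  A1 <- add_bias(Hcat %*% P$hd_W1, P$hd_b1)
  H1 <- relu(A1)
  m1 <- if (training) dropout_mask(nrow(H1), ncol(H1), dropout) else NULL
  H1d <- apply_mask(H1, m1)
  A2 <- add_bias(H1d %*% P$hd_W2, P$hd_b2)
  H2 <- relu(A2)
  m2 <- if (training) dropout_mask(nrow(H2), ncol(H2), dropout) else NULL
  H2d <- apply_mask(H2, m2)
  logit <- unname(drop(H2d %*% P$hd_W3)) + P$hd_b3

  cache <- list(ce = ce, ca = ca, cl = cl, Z = Z, ZW = ZW,
                pre_raw = pre_raw, alpha = alpha, Mb = Mb, E = E,
                Au = Au, Av = Av, cr = cr, Hcat = Hcat, A1 = A1,
                H1d = H1d, m1 = m1, A2 = A2, H2d = H2d, m2 = m2,
                graph = graph, batch_idx = batch_idx,
                edge_dim = ncol(edge_feat))
  list(prob = sigmoid(logit), logit = logit, cache = cache)
}

#' Backward pass; returns gradients for every parameter
#' @param params parameter list
#' @param cache from \code{nn_forward}
#' @param dlogit gradient of the loss w.r.t. each logit
#' @keywords internal
nn_backward <- function(params, cache, dlogit) {
  P <- params; C <- cache
  graph <- C$graph
  n <- graph$n
  dlogit <- cbind(dlogit)

  # head
  dhd_W3 <- crossprod(C$H2d, dlogit)
  dhd_b3 <- colSums(dlogit)
  dH2d <- dlogit %*% t(P$hd_W3)
  dH2 <- apply_mask(dH2d, C$m2)
  dA2 <- dH2 * (C$A2 > 0)
  dhd_W2 <- crossprod(C$H1d, dA2)
  dhd_b2 <- colSums(dA2)
  dH1d <- dA2 %*% t(P$hd_W2)
  dH1 <- apply_mask(dH1d, C$m1)
  dA1 <- dH1 * (C$A1 > 0)
  dhd_W1 <- crossprod(C$Hcat, dA1)
  dhd_b1 <- colSums(dA1)
  dHcat <- dA1 %*% t(P$hd_W1)
  d <- ncol(C$Z)
  dR <- dHcat[, seq_len(d), drop = FALSE]

  # rho
  br <- ff2_backward(C$cr, dR, P$rho_W1, P$rho_W2)
  dS <- br$dX

  # phi on both endpoints
  dAu <- dS * (C$Au > 0)
  dAv <- dS * (C$Av > 0)
  u <- C$batch_idx[, 1]; v <- C$batch_idx[, 2]
  Eu <- C$E[u, , drop = FALSE]; Ev <- C$E[v, , drop = FALSE]
  dphi_W <- crossprod(Eu, dAu) + crossprod(Ev, dAv)
  dphi_b <- colSums(dAu) + colSums(dAv)
  dE <- scatter_sum(rbind(dAu %*% t(P$phi_W), dAv %*% t(P$phi_W)),
                    c(u, v), n)

  # graph attention
  dMb <- dE * (C$Mb > 0)
  dgat_b <- colSums(dMb)
  ZW <- C$ZW; alpha <- C$alpha
  src <- graph$src; dst <- graph$dst
  dalpha <- rowSums(dMb[dst, , drop = FALSE] * ZW[src, , drop = FALSE])
  dZW <- scatter_sum(alpha * dMb[dst, , drop = FALSE], src, n)
  sgrp <- drop(scatter_sum(cbind(alpha * dalpha), dst, n))
  de <- alpha * (dalpha - sgrp[dst])
  dpre <- de * ifelse(C$pre_raw > 0, 1, 0.2)
  dgat_asrc <- drop(crossprod(ZW[src, , drop = FALSE], dpre))
  dgat_adst <- drop(crossprod(ZW[dst, , drop = FALSE], dpre))
  # grad via a_src/a_dst factors through the scatter: sum dpre per node first
  dps <- drop(scatter_sum(cbind(dpre), src, n))
  dpd <- drop(scatter_sum(cbind(dpre), dst, n))
  dZW <- dZW + outer(dps, P$gat_asrc) + outer(dpd, P$gat_adst)
  dgat_W <- crossprod(C$Z, dZW)
  dZ <- dZW %*% t(P$gat_W) + dMb  # second term: the residual path

  # projection blocks
  be <- ff2_backward(C$ce, dZ, P$pe_W1, P$pe_W2)
  ba <- ff2_backward(C$ca, dZ, P$pa_W1, P$pa_W2)
  bl <- ff2_backward(C$cl, dZ, P$pl_W1, P$pl_W2)

  list(
    pe_W1 = be$dW1, pe_b1 = be$db1, pe_W2 = be$dW2, pe_b2 = be$db2,
    pa_W1 = ba$dW1, pa_b1 = ba$db1, pa_W2 = ba$dW2, pa_b2 = ba$db2,
    pl_W1 = bl$dW1, pl_b1 = bl$db1, pl_W2 = bl$dW2, pl_b2 = bl$db2,
    gat_W = dgat_W, gat_asrc = dgat_asrc, gat_adst = dgat_adst,
    gat_b = dgat_b,
    phi_W = dphi_W, phi_b = dphi_b,
    rho_W1 = br$dW1, rho_b1 = br$db1, rho_W2 = br$dW2, rho_b2 = br$db2,
    hd_W1 = dhd_W1, hd_b1 = dhd_b1, hd_W2 = dhd_W2, hd_b2 = dhd_b2,
    hd_W3 = dhd_W3, hd_b3 = dhd_b3
  )
}

#' Numerically stable mean binary cross-entropy from logits
#' @keywords internal
bce_loss <- function(logit, y) {
  mean(pmax(logit, 0) - y * logit + log1p(exp(-abs(logit))))
}

# gradient of mean BCE w.r.t. logits
bce_grad <- function(logit, y) (sigmoid(logit) - y) / length(y)

#' Adam optimizer state and step
#'
#' L2 weight decay is folded into the gradient (decoupled decay is not
#' used), matching the common Adam-with-weight-decay convention.
#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      frozen = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    gr <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
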