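# Internal dense-network primitives shared by the VAE and S-VQ-VAE.
#
# Parameters live in a flat named list of matrices/vectors ("enc1.W",
# "enc1.b", ..., "out.W", "out.b"); samples are rows, so a layer is
# A %*% W + b with W of shape (in x out). All gradients are derived by hand;
# the Adam optimizer operates on the flat list.

.initLayer <- function(fanin, fanout) {
  lim <- 1 / sqrt(fanin)
  list(W = matrix(stats::runif(fanin * fanout, -lim, lim), fanin, fanout),
       b = rep(0, fanout))
}

.affine <- function(A, params, name) {
  sweep(A %*% params[[paste0(name, ".W")]], 2,
        params[[paste0(name, ".b")]], "+")
}

# tanh hidden stack; returns list of post-activation matrices (incl. input
# as element 1) for backprop
.tanhStack <- function(A, params, prefix, nLayers) {
  acts <- vector("list", nLayers + 1L)
  acts[[1L]] <- A
  for (i in seq_len(nLayers))
    acts[[i + 1L]] <- tanh(.affine(acts[[i]], params, paste0(prefix, i)))
  acts
}

# backprop through a tanh stack given dL/d(last activation); returns
# gradients (appended to `grads`) and dL/d(stack input)
.tanhStackBackward <- function(G, acts, params, prefix, nLayers, grads) {
  for (i in rev(seq_len(nLayers))) {
    Gz <- G * (1 - acts[[i + 1L]]^2)
    nm <- paste0(prefix, i)
    grads[[paste0(nm, ".W")]] <- crossprod(acts[[i]], Gz)
    grads[[paste0(nm, ".b")]] <- colSums(Gz)
    G <- Gz %*% t(params[[paste0(nm, ".W")]])
  }
  list(grads = grads, dInput = G)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# deterministic train/validation split of n samples
.splitIdx <- function(n, trainFraction, seed, strata = NULL) {
  set.seed(seed)
  if (is.null(strata)) {
    perm <- sample.int(n)
    nTrain <- max(1L, floor(trainFraction * n))
    return(list(train = sort(perm[seq_len(nTrain)]),
                val = sort(perm[-seq_len(nTrain)])))
  }
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    k <- max(1L, floor(trainFraction * length(idx)))
    train <- c(train, idx[seq_len(k)])
  }
  list(train = sort(train), val = sort(setdiff(seq_len(n), train)))
}
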