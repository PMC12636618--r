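# Mixture density network core: a small fully-connected backbone with three
# readout heads (mixture weights, component means, component spreads), the
# maximum-likelihood training objectives (von Mises / Gaussian mixture NLL and
# the categorical cross-entropy baseline), analytic backpropagation through
# the constraint transforms, an Adam optimizer with a warmup/decay learning
# rate schedule, and mirror augmentation.

#' Construct a mixture density network
#'
#' A fully-connected backbone (rectified linear hidden layers) whose final
#' hidden representation feeds three linear readout heads. Depending on
#' `readout`, the heads parameterize a von Mises mixture over
#' (azimuth, elevation), a Gaussian mixture over log-f0, or a categorical
#' distribution over discrete location bins (the cross-entropy baseline).
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of hidden layer widths.
#' @param K number of mixture components (default 5).
#' @param readout one of `"von_mises_mixture"`, `"gaussian_mixture"`,
#'   `"categorical"`.
#' @param n_classes number of classes for the categorical readout.
#' @param bounds readout bounds, see [readout_bounds()].
#' @param seed integer seed for weight initialization.
#' @return object of class `mdn_network`.
#' @export
mdn_network <- function(input_dim, hidden = c(32, 32), K = 5,
                        readout = c("von_mises_mixture", "gaussian_mixture",
                                    "categorical"),
                        n_classes = NULL, bounds = readout_bounds(),
                        seed = 1) {
  readout <- match.arg(readout)
  old <- local_seed(seed); on.exit(restore_seed(old))
  dims <- c(input_dim, hidden)
  layers <- list()
  for (l in seq_along(hidden)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                 dims[l], dims[l + 1]),
      b = numeric(dims[l + 1]))
  }
  h <- utils::tail(dims, 1)
  lin <- function(nout, sd = sqrt(1 / h), bias = 0)
    list(W = matrix(stats::rnorm(h * nout, sd = sd), h, nout),
         b = rep(bias, length.out = nout))
  heads <- switch(readout,
    von_mises_mixture = list(
      alpha = lin(K),
      mean = lin(4 * K, sd = 0.5 / sqrt(h)),
      # concentrations initialized mid-range so the bounded rectifier passes
      # gradient at the start of training
      conc = {
        hd <- lin(2 * K, sd = 0.5 / sqrt(h))
        hd$b <- stats::runif(2 * K, 4, 30)
        hd
      }),
    gaussian_mixture = list(
      alpha = lin(K),
      mean = {
        hd <- lin(K, sd = 0.5 / sqrt(h))
        hd$b <- seq(bounds$mean_lb_logf0 + 0.5, bounds$mean_ub_logf0 - 0.5,
                    length.out = K)
        hd
      },
      var = {
        hd <- lin(K, sd = 0.5 / sqrt(h))
        hd$b <- rep(-0.5, K)
        hd
      }),
    categorical = {
      if (is.null(n_classes)) stop("categorical readout needs n_classes")
      list(logits = lin(n_classes))
    })
  structure(list(readout = readout, K = K, n_classes = n_classes,
                 input_dim = input_dim, hidden = hidden, bounds = bounds,
                 layers = layers, heads = heads),
            class = "mdn_network")
}

relu <- function(x) { x[x < 0] <- 0; x }

# forward through the backbone; returns hidden activations per layer
backbone_forward <- function(net, X) {
  acts <- vector("list", length(net$layers) + 1)
  acts[[1]] <- X
  H <- X
  for (l in seq_along(net$layers)) {
    H <- relu(sweep(H %*% net$layers[[l]]$W, 2, -net$layers[[l]]$b))
    acts[[l + 1]] <- H
  }
  acts
}

head_raw <- function(hd, H) sweep(H %*% hd$W, 2, -hd$b)

#' Forward pass: network outputs as constrained mixture parameters
#'
#' Applies all constraint transforms: softmax for weights, tanh + atan2 for
#' circular means, the bounded rectifier for concentrations and log-f0 means,
#' softplus + epsilon for variances.
#'
#' @param net an [mdn_network()].
#' @param X n x input_dim feature matrix (a single feature vector is
#'   accepted).
#' @return list of constrained parameter matrices (n rows each); for
#'   `von_mises_mixture`: `alpha`, `mu_az`, `mu_el`, `kappa_az`, `kappa_el`;
#'   for `gaussian_mixture`: `alpha`, `mu`, `sigma2`; for `categorical`:
#'   `prob`.
#' @export
mdn_forward <- function(net, X) {
  X <- matrix(X, ncol = net$input_dim)
  H <- utils::tail(backbone_forward(net, X), 1)[[1]]
  K <- net$K
  b <- net$bounds
  if (net$readout == "von_mises_mixture") {
    A <- head_raw(net$heads$alpha, H)
    M <- head_raw(net$heads$mean, H)
    C <- head_raw(net$heads$conc, H)
    alpha <- t(apply(A, 1, constrain_weights))
    if (K == 1) alpha <- matrix(alpha, ncol = 1)
    u_az <- M[, 4 * (1:K) - 3, drop = FALSE]; v_az <- M[, 4 * (1:K) - 2, drop = FALSE]
    u_el <- M[, 4 * (1:K) - 1, drop = FALSE]; v_el <- M[, 4 * (1:K), drop = FALSE]
    list(alpha = alpha,
         mu_az = atan2(tanh(u_az), tanh(v_az)),
         mu_el = atan2(tanh(u_el), tanh(v_el)),
         kappa_az = relux(C[, 2 * (1:K) - 1, drop = FALSE], b$conc_lb, b$conc_ub),
         kappa_el = relux(C[, 2 * (1:K), drop = FALSE], b$conc_lb, b$conc_ub))
  } else if (net$readout == "gaussian_mixture") {
    A <- head_raw(net$heads$alpha, H)
    alpha <- t(apply(A, 1, constrain_weights))
    if (K == 1) alpha <- matrix(alpha, ncol = 1)
    list(alpha = alpha,
         mu = relux(head_raw(net$heads$mean, H), b$mean_lb_logf0, b$mean_ub_logf0),
         sigma2 = constrain_variance(head_raw(net$heads$var, H), b$var_epsilon))
  } else {
    L <- head_raw(net$heads$logits, H)
    list(prob = exp(L - row_logsumexp(L)))
  }
}

#' Extract the predicted mixture for one input
#'
#' @param net an [mdn_network()].
#' @param x single feature vector.
#' @return a [von_mises_mixture()] or [gaussian_mixture_1d()] (or a
#'   probability vector for the categorical readout).
#' @export
mdn_predict_mixture <- function(net, x) {
  p <- mdn_forward(net, matrix(x, nrow = 1))
  if (net$readout == "von_mises_mixture") {
    von_mises_mixture(p$alpha[1, ], cbind(p$mu_az[1, ], p$mu_el[1, ]),
                      cbind(p$kappa_az[1, ], p$kappa_el[1, ]), net$bounds)
  } else if (net$readout == "gaussian_mixture") {
    gaussian_mixture_1d(p$alpha[1, ], p$mu[1, ], p$sigma2[1, ], net$bounds)
  } else p$prob[1, ]
}

# ---- losses and analytic gradients w.r.t. raw head outputs ---------------

# von Mises mixture NLL for a batch; Y is n x 2 (azimuth, elevation radians).
# Returns loss and, if grad=TRUE, gradients w.r.t. the raw head outputs.
vm_nll_raw <- function(net, H, Y, grad = FALSE) {
  K <- net$K; b <- net$bounds; n <- nrow(H)
  A <- head_raw(net$heads$alpha, H)
  M <- head_raw(net$heads$mean, H)
  C <- head_raw(net$heads$conc, H)
  logalpha <- A - row_logsumexp(A)
  alpha <- exp(logalpha)
  iu_az <- 4 * (1:K) - 3; iv_az <- 4 * (1:K) - 2
  iu_el <- 4 * (1:K) - 1; iv_el <- 4 * (1:K)
  s_az <- tanh(M[, iu_az, drop = FALSE]); c_az <- tanh(M[, iv_az, drop = FALSE])
  s_el <- tanh(M[, iu_el, drop = FALSE]); c_el <- tanh(M[, iv_el, drop = FALSE])
  mu_az <- atan2(s_az, c_az); mu_el <- atan2(s_el, c_el)
  ic_az <- 2 * (1:K) - 1; ic_el <- 2 * (1:K)
  k_az <- relux(C[, ic_az, drop = FALSE], b$conc_lb, b$conc_ub)
  k_el <- relux(C[, ic_el, drop = FALSE], b$conc_lb, b$conc_ub)
  d_az <- Y[, 1] - mu_az   # n x K (recycled column)
  d_el <- Y[, 2] - mu_el
  g <- logalpha +
    k_az * cos(d_az) - matrix(log_i0(k_az), n, K) +
    k_el * cos(d_el) - matrix(log_i0(k_el), n, K) - 2 * log(2 * pi)
  ll <- row_logsumexp(g)
  loss <- -mean(ll)
  if (!grad) return(list(loss = loss))
  r <- exp(g - ll)                     # responsibilities, n x K
  sc <- 1 / n
  dA <- (alpha - r) * sc
  # means
  dmu_az <- -r * k_az * sin(d_az) * sc
  dmu_el <- -r * k_el * sin(d_el) * sc
  dM <- matrix(0, n, 4 * K)
  den_az <- s_az^2 + c_az^2; den_el <- s_el^2 + c_el^2
  dM[, iu_az] <- dmu_az * (c_az / den_az) * (1 - s_az^2)
  dM[, iv_az] <- dmu_az * (-s_az / den_az) * (1 - c_az^2)
  dM[, iu_el] <- dmu_el * (c_el / den_el) * (1 - s_el^2)
  dM[, iv_el] <- dmu_el * (-s_el / den_el) * (1 - c_el^2)
  # concentrations (zero gradient where the bounded rectifier clips)
  dC <- matrix(0, n, 2 * K)
  A_az <- matrix(bessel_ratio_i1_i0(k_az), n, K)
  A_el <- matrix(bessel_ratio_i1_i0(k_el), n, K)
  pass_az <- (C[, ic_az, drop = FALSE] > b$conc_lb) & (C[, ic_az, drop = FALSE] < b$conc_ub)
  pass_el <- (C[, ic_el, drop = FALSE] > b$conc_lb) & (C[, ic_el, drop = FALSE] < b$conc_ub)
  dC[, ic_az] <- -r * (cos(d_az) - A_az) * pass_az * sc
  dC[, ic_el] <- -r * (cos(d_el) - A_el) * pass_el * sc
  list(loss = loss, d = list(alpha = dA, mean = dM, conc = dC))
}

# Gaussian mixture NLL for a batch; y is a numeric vector of log-f0 targets.
gm_nll_raw <- function(net, H, y, grad = FALSE) {
  K <- net$K; b <- net$bounds; n <- nrow(H)
  A <- head_raw(net$heads$alpha, H)
  Mr <- head_raw(net$heads$mean, H)
  Vr <- head_raw(net$heads$var, H)
  logalpha <- A - row_logsumexp(A)
  alpha <- exp(logalpha)
  mu <- relux(Mr, b$mean_lb_logf0, b$mean_ub_logf0)
  s2 <- constrain_variance(Vr, b$var_epsilon)
  d <- y - mu
  g <- logalpha - 0.5 * log(2 * pi * s2) - d^2 / (2 * s2)
  ll <- row_logsumexp(g)
  loss <- -mean(ll)
  if (!grad) return(list(loss = loss))
  r <- exp(g - ll)
  sc <- 1 / n
  dA <- (alpha - r) * sc
  pass <- (Mr > b$mean_lb_logf0) & (Mr < b$mean_ub_logf0)
  dMu <- -r * d / s2 * pass * sc
  ds2 <- -r * (d^2 / (2 * s2^2) - 1 / (2 * s2)) * sc
  dVr <- ds2 * stats::plogis(Vr)       # d softplus / d v = sigmoid(v)
  list(loss = loss, d = list(alpha = dA, mean = dMu, var = dVr))
}

ce_raw <- function(net, H, class_idx, grad = FALSE) {
  L <- head_raw(net$heads$logits, H)
  logp <- L - row_logsumexp(L)
  n <- nrow(L)
  picked <- logp[cbind(seq_len(n), class_idx)]
  loss <- -mean(picked)
  if (!grad) return(list(loss = loss))
  dL <- exp(logp)
  dL[cbind(seq_len(n), class_idx)] <- dL[cbind(seq_len(n), class_idx)] - 1
  list(loss = loss, d = list(logits = dL / n))
}

#' Mixture NLL loss of a batch
#'
#' Mean negative log-likelihood of the labels under the network's predicted
#' mixtures.
#'
#' @param net an [mdn_network()] with a mixture readout.
#' @param X n x input_dim feature matrix.
#' @param Y labels: n x 2 radians for the von Mises readout, length-n log-f0
#'   vector for the Gaussian readout.
#' @return scalar mean NLL.
#' @export
nll_loss <- function(net, X, Y) {
  X <- matrix(X, ncol = net$input_dim)
  H <- utils::tail(backbone_forward(net, X), 1)[[1]]
  loss <- switch(net$readout,
    von_mises_mixture = vm_nll_raw(net, H, matrix(Y, ncol = 2))$loss,
    gaussian_mixture  = gm_nll_raw(net, H, as.numeric(Y))$loss,
    stop("nll_loss requires a mixture readout"))
  if (!is.finite(loss)) stop("non-finite NLL loss")
  loss
}

#' Cross-entropy loss of a batch (categorical baseline)
#'
#' @param net an [mdn_network()] with the categorical readout.
#' @param X n x input_dim feature matrix.
#' @param class_idx integer class labels in 1..n_classes.
#' @return scalar mean cross-entropy.
#' @export
cross_entropy_loss <- function(net, X, class_idx) {
  if (net$readout != "categorical") stop("categorical readout required")
  X <- matrix(X, ncol = net$input_dim)
  H <- utils::tail(backbone_forward(net, X), 1)[[1]]
  ce_raw(net, H, as.integer(class_idx))$loss
}

# full backward pass; returns gradients shaped like the parameters
mdn_gradients <- function(net, X, Y) {
  acts <- backbone_forward(net, X)
  H <- acts[[length(acts)]]
  res <- switch(net$readout,
    von_mises_mixture = vm_nll_raw(net, H, Y, grad = TRUE),
    gaussian_mixture  = gm_nll_raw(net, H, Y, grad = TRUE),
    categorical       = ce_raw(net, H, Y, grad = TRUE))
  grads <- list(layers = vector("list", length(net$layers)),
                heads = list())
  dH <- matrix(0, nrow(H), ncol(H))
  for (hn in names(res$d)) {
    dRaw <- res$d[[hn]]
    grads$heads[[hn]] <- list(W = crossprod(H, dRaw), b = colSums(dRaw))
    dH <- dH + dRaw %*% t(net$heads[[hn]]$W)
  }
  for (l in rev(seq_along(net$layers))) {
    dZ <- dH * (acts[[l + 1]] > 0)
    grads$layers[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    dH <- dZ %*% t(net$layers[[l]]$W)
  }
  list(loss = res$loss, grads = grads)
}

#' Training configuration
#'
#' Defaults follow the two training recipes of the readouts: Adam with
#' initial learning rate 0.001; for the localization task 20% of steps linear
#' warmup and 20% decay with multiplicative factor 0.9 per decay step, batch
#' size 64; for the pitch task 10% warmup, 20% decay with factor 0.99, batch
#' size 128.
#'
#' @param task `"localization"` or `"pitch"` (sets the defaults).
#' @param lr initial learning rate.
#' @param warmup_fraction,decay_fraction fractions of total steps.
#' @param decay_gamma multiplicative decay factor applied per decay step.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs.
#' @param patience epochs of relative improvement < `min_rel_improvement`
#'   before early stopping.
#' @param min_rel_improvement early-stop threshold on relative loss change.
#' @param seed integer seed controlling data order and any augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(task = c("localization", "pitch"), lr = 0.001,
                         warmup_fraction = NULL, decay_fraction = 0.2,
                         decay_gamma = NULL, batch_size = NULL,
                         max_epochs = NULL, patience = 1,
                         min_rel_improvement = 1e-4, seed = 1) {
  task <- match.arg(task)
  cfg <- list(task = task, lr = lr,
              warmup_fraction = warmup_fraction %||%
                if (task == "localization") 0.2 else 0.1,
              decay_fraction = decay_fraction,
              decay_gamma = decay_gamma %||%
                if (task == "localization") 0.9 else 0.99,
              batch_size = batch_size %||%
                if (task == "localization") 64L else 128L,
              max_epochs = max_epochs %||%
                if (task == "localization") 5L else 25L,
              patience = patience, min_rel_improvement = min_rel_improvement,
              seed = seed)
  if (cfg$warmup_fraction + cfg$decay_fraction > 1)
    stop("warmup_fraction + decay_fraction must be <= 1")
  class(cfg) <- "train_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Learning rate schedule: linear warmup, plateau, multiplicative decay
#'
#' @param step 0-based step index.
#' @param total_steps total number of steps.
#' @param cfg a [train_config()].
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, cfg) {
  w <- floor(cfg$warmup_fraction * total_steps)
  d0 <- total_steps - floor(cfg$decay_fraction * total_steps)
  if (step < w) return(cfg$lr * step / max(w, 1))
  if (step < d0) return(cfg$lr)
  cfg$lr * cfg$decay_gamma^(step - d0 + 1)
}

adam_init <- function(params) rapply(params, function(p) p * 0, how = "replace")

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b")) {
      g <- grads$layers[[l]][[nm]]
      m <- beta1 * state$m$layers[[l]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v$layers[[l]][[nm]] + (1 - beta2) * g^2
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
      state$m$layers[[l]][[nm]] <- m
      state$v$layers[[l]][[nm]] <- v
    }
  }
  for (hn in names(grads$heads)) {
    for (nm in c("W", "b")) {
      g <- grads$heads[[hn]][[nm]]
      m <- beta1 * state$m$heads[[hn]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v$heads[[hn]][[nm]] + (1 - beta2) * g^2
      net$heads[[hn]][[nm]] <- net$heads[[hn]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
      state$m$heads[[hn]][[nm]] <- m
      state$v$heads[[hn]][[nm]] <- v
    }
  }
  list(net = net, state = state)
}

#' Train a mixture density network
#'
#' Minibatch Adam with the warmup/plateau/decay schedule of
#' [lr_schedule()], deterministic data order given `cfg$seed`, early stopping
#' when the relative improvement of the epoch-mean loss falls below
#' `cfg$min_rel_improvement` for `cfg$patience` consecutive epochs, and abort
#' with the last finite checkpoint if the loss diverges.
#'
#' @param net an [mdn_network()].
#' @param X n x input_dim feature matrix.
#' @param Y labels (see [nll_loss()]); integer classes for the categorical
#'   readout.
#' @param cfg a [train_config()].
#' @return list with elements `net` (trained), `trace` (per-step losses),
#'   `epoch_loss`, `lr` (per-step learning rates).
#' @export
train_mdn <- function(net, X, Y, cfg = train_config("localization")) {
  X <- matrix(X, ncol = net$input_dim)
  n <- nrow(X)
  if (n == 0) stop("empty dataset")
  is_vm <- net$readout == "von_mises_mixture"
  Ym <- if (is_vm) matrix(Y, ncol = 2) else Y
  steps_per_epoch <- max(1L, floor(n / cfg$batch_size))
  total_steps <- steps_per_epoch * cfg$max_epochs
  state <- list(t = 0,
                m = list(layers = lapply(net$layers, function(l) lapply(l, function(p) p * 0)),
                         heads = lapply(net$heads, function(l) lapply(l, function(p) p * 0))),
                v = list(layers = lapply(net$layers, function(l) lapply(l, function(p) p * 0)),
                         heads = lapply(net$heads, function(l) lapply(l, function(p) p * 0))))
  old <- local_seed(cfg$seed); on.exit(restore_seed(old))
  trace <- numeric(0); lrs <- numeric(0); epoch_loss <- numeric(0)
  best <- net; prev_epoch <- Inf; bad <- 0L; step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1) * cfg$batch_size + 1):min(s * cfg$batch_size, n)]
      Yb <- if (is_vm) Ym[idx, , drop = FALSE] else Ym[idx]
      res <- mdn_gradients(net, X[idx, , drop = FALSE], Yb)
      if (!is.finite(res$loss)) {
        warning("training diverged (non-finite loss); returning last good checkpoint")
        return(list(net = best, trace = trace, epoch_loss = epoch_loss, lr = lrs))
      }
      lr_t <- lr_schedule(step, total_steps, cfg)
      st <- adam_step(net, res$grads, state, lr_t)
      net <- st$net; state <- st$state
      trace <- c(trace, res$loss); lrs <- c(lrs, lr_t)
      ep_losses <- c(ep_losses, res$loss)
      step <- step + 1L
    }
    el <- mean(ep_losses)
    epoch_loss <- c(epoch_loss, el)
    best <- net
    rel <- (prev_epoch - el) / max(abs(prev_epoch), 1e-12)
    if (is.finite(prev_epoch) && rel < cfg$min_rel_improvement) {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    } else bad <- 0L
    prev_epoch <- el
  }
  list(net = net, trace = trace, epoch_loss = epoch_loss, lr = lrs)
}

# ---- discrete location grid and augmentation -----------------------------

#' The 504-bin location grid of the categorical baseline
#'
#' Azimuths every 5 degrees spanning 0-355 (72 values) crossed with
#' elevations every 10 degrees spanning 0-60 (7 values), azimuth-major order.
#'
#' @return data.frame with columns `azimuth`, `elevation` (degrees), 504 rows.
#' @export
location_grid_504 <- function() {
  az <- seq(0, 355, by = 5)
  el <- seq(0, 60, by = 10)
  data.frame(azimuth = rep(az, each = length(el)),
             elevation = rep(el, times = length(az)))
}

#' Snap a location to the nearest grid bin
#'
#' @param azimuth,elevation degrees.
#' @param grid a location grid data.frame (default [location_grid_504()]).
#' @return integer row index into `grid`; warns if the location is off-grid.
#' @export
nearest_grid_bin <- function(azimuth, elevation, grid = location_grid_504()) {
  daz <- abs(wrap_deg_180(grid$azimuth - azimuth))
  del <- abs(grid$elevation - elevation)
  i <- which.min(daz^2 + del^2)
  if (daz[i] > 1e-6 || del[i] > 1e-6)
    warning("label off-grid; assigned to nearest bin")
  i
}

#' Mirror a labeled scene across the interaural axis
#'
#' Swaps the left and right channels of a binaural cochleagram (or stereo
#' waveform) and reflects the azimuth label across the midline:
#' `az -> (360 - az) mod 360`; elevation is unchanged. Applying the operation
#' twice returns the original scene.
#'
#' @param scene list with elements `cochleagram` (ears x channels x time
#'   array) or `waveform` (samples x 2), plus `azimuth` and `elevation`
#'   labels in degrees.
#' @return the mirrored scene.
#' @export
mirror_scene <- function(scene) {
  if (!is.null(scene$cochleagram)) {
    cg <- scene$cochleagram
    if (length(dim(cg)) != 3) stop("mirror requires a binaural cochleagram")
    scene$cochleagram <- structure(cg[c(2, 1), , , drop = FALSE],
                                   cfs = attr(cg, "cfs"), rate = attr(cg, "rate"),
                                   class = class(cg))
  } else if (!is.null(scene$waveform)) {
    if (ncol(scene$waveform) != 2) stop("mirror requires a stereo waveform")
    scene$waveform <- scene$waveform[, c(2, 1)]
  } else stop("scene must contain a cochleagram or waveform")
  scene$azimuth <- (360 - scene$azimuth) %% 360
  scene
}
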