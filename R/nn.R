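# ---------------------------------------------------------------------------
# Minimal neural-network module system on top of the autodiff engine.
# A module is an environment carrying named parameter tensors, named plain
# buffers (e.g. batch-norm running statistics), child modules and a
# `forward(x, train)` closure.
# ---------------------------------------------------------------------------

nn_module <- function(cls) {
  m <- new.env(parent = emptyenv())
  m$.params <- list()
  m$.buffers <- list()
  m$.children <- list()
  class(m) <- c(cls, "nn_module")
  m
}

nn_param <- function(m, name, value) {
  t <- ag_tensor(value, requires_grad = TRUE)
  m$.params[[name]] <- t
  t
}

nn_child <- function(m, name, child) {
  m$.children[[name]] <- child
  child
}

#' Collect all trainable parameter tensors of a model
#' @param m a model built by [build_model()] (or any internal module).
#' @return flat named list of `ag_tensor`s.
#' @export
nn_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$.params)) out[[paste0(prefix, nm)]] <- m$.params[[nm]]
  for (nm in names(m$.children)) {
    out <- c(out, nn_parameters(m$.children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

# Named list of buffer values (copied), recursively. Each buffer entry is an
# environment holding `st` (the owning state env) and `field` (its name there).
nn_buffers <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$.buffers)) {
    e <- m$.buffers[[nm]]
    out[[paste0(prefix, nm)]] <- e$st[[e$field]]
  }
  for (nm in names(m$.children)) {
    out <- c(out, nn_buffers(m$.children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

nn_buffer_envs <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$.buffers)) out[[paste0(prefix, nm)]] <- m$.buffers[[nm]]
  for (nm in names(m$.children)) {
    out <- c(out, nn_buffer_envs(m$.children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Total number of scalar parameters in a model
#' @param m a model module.
#' @return integer count of trainable scalars.
#' @export
n_parameters <- function(m) {
  sum(vapply(nn_parameters(m), function(p) length(p$value), numeric(1)))
}

# --- random initialisation --------------------------------------------------

init_conv_weight <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, 0, sd), dim = c(kh, kw, cin, cout))
}

init_linear_weight <- function(cin, cout) {
  lim <- sqrt(6 / (cin + cout))
  matrix(stats::runif(cin * cout, -lim, lim), cin, cout)
}

# --- layers -----------------------------------------------------------------

# Conv + BatchNorm + activation ("CBL"). With `bn = FALSE` the convolution
# carries a learnable bias instead (used for detection heads).
nn_cbl <- function(cin, cout, k = 3, stride = 1, act = "silu", bn = TRUE,
                   bias_init = NULL) {
  m <- nn_module("nn_cbl")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$act <- act; m$bn <- bn
  w <- nn_param(m, "weight", init_conv_weight(k, k, cin, cout))
  b <- if (bn) ag_tensor(numeric(cout)) else {
    nn_param(m, "bias", if (is.null(bias_init)) numeric(cout) else bias_init)
  }
  if (bn) {
    gamma <- nn_param(m, "gamma", rep(1, cout))
    beta <- nn_param(m, "beta", numeric(cout))
    bnst <- new.env(parent = emptyenv())
    bnst$running_mean <- numeric(cout)
    bnst$running_var <- rep(1, cout)
    bnst$momentum <- 0.03
    bnst$eps <- 1e-3
    for (f in c("running_mean", "running_var")) {
      e <- new.env(parent = emptyenv())
      e$st <- bnst
      e$field <- f
      m$.buffers[[f]] <- e
    }
    m$bn_state <- bnst
  }
  m$forward <- function(x, train = FALSE) {
    y <- ag_conv2d(x, w, b, stride)
    if (bn) y <- ag_batchnorm_hwcn(y, gamma, beta, m$bn_state, train)
    switch(m$act,
           silu = ag_silu(y),
           relu = ag_relu(y),
           none = y,
           stop("unknown activation: ", m$act))
  }
  m
}

nn_linear <- function(cin, cout, bias = TRUE) {
  m <- nn_module("nn_linear")
  w <- nn_param(m, "weight", init_linear_weight(cin, cout))
  b <- if (bias) nn_param(m, "bias", numeric(cout)) else NULL
  m$forward <- function(x, train = FALSE) ag_linear(x, w, b)
  m
}

# --- optimizer --------------------------------------------------------------

#' Create an Adam optimizer over a parameter list
#'
#' Adaptive-moment estimation with bias correction; parameters are updated
#' in place.
#'
#' @param params named list of `ag_tensor`s (from [nn_parameters()]).
#' @param lr learning rate.
#' @param betas first/second moment decay rates.
#' @param eps numerical stabiliser.
#' @return an optimizer object; advance it with [optim_step()].
#' @export
optim_adam <- function(params, lr = 0.01, betas = c(0.9, 0.999), eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- lr
  o$b1 <- betas[1]; o$b2 <- betas[2]; o$eps <- eps
  o$t <- 0L
  o$m <- lapply(params, function(p) array(0, dim = dim1(p$value)))
  o$v <- lapply(params, function(p) array(0, dim = dim1(p$value)))
  class(o) <- "wd_optim_adam"
  o
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Apply one Adam update step
#' @param o optimizer from [optim_adam()].
#' @param lr optional learning-rate override for this step.
#' @export
optim_step <- function(o, lr = NULL) {
  if (is.null(lr)) lr <- o$lr
  o$t <- o$t + 1L
  bc1 <- 1 - o$b1^o$t
  bc2 <- 1 - o$b2^o$t
  for (i in seq_along(o$params)) {
    p <- o$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    o$m[[i]] <- o$b1 * o$m[[i]] + (1 - o$b1) * g
    o$v[[i]] <- o$b2 * o$v[[i]] + (1 - o$b2) * g * g
    mhat <- o$m[[i]] / bc1
    vhat <- o$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + o$eps)
  }
  invisible(o)
}

# --- state (checkpoint) helpers --------------------------------------------

model_state <- function(model) {
  list(params = lapply(nn_parameters(model), function(p) p$value),
       buffers = nn_buffers(model))
}

load_model_state <- function(model, state) {
  ps <- nn_parameters(model)
  for (nm in names(state$params)) {
    if (is.null(ps[[nm]])) stop("unknown parameter in checkpoint: ", nm)
    stopifnot(length(ps[[nm]]$value) == length(state$params[[nm]]))
    v <- state$params[[nm]]
    dim(v) <- dim(ps[[nm]]$value)
    ps[[nm]]$value <- v
  }
  bes <- nn_buffer_envs(model)
  for (nm in names(state$buffers)) {
    e <- bes[[nm]]
    if (!is.null(e)) e$st[[e$field]] <- state$buffers[[nm]]
  }
  invisible(model)
}
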