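#' @useDynLib wildetect, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# A compact reverse-mode automatic-differentiation engine.
#
# A tensor is an environment holding `value` (a numeric array), an optional
# accumulated `grad`, the list of parent tensors and a backward closure that
# maps the incoming gradient to one gradient per parent. The tape is the
# implicit DAG of parents; `ag_backward()` topologically sorts it and
# accumulates gradients. Nodes whose ancestors hold no trainable parameters
# are pruned at construction time, so evaluation-mode forward passes carry
# no tape at all.
# ---------------------------------------------------------------------------

.ag_state <- new.env(parent = emptyenv())
.ag_state$tag <- 0L

new_ag <- function(value, requires_grad, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- parents
  e$backward_fn <- backward
  class(e) <- "ag_tensor"
  e
}

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a node of the automatic-differentiation tape.
#' Leaves created with `requires_grad = TRUE` accumulate gradients in `$grad`
#' after [ag_backward()].
#'
#' @param value numeric vector/matrix/array.
#' @param requires_grad should gradients be accumulated for this leaf?
#' @return an `ag_tensor` (environment with `value`, `grad` fields).
#' @export
ag_tensor <- function(value, requires_grad = FALSE) {
  new_ag(value, requires_grad, list(), NULL)
}

# Coerce plain numerics to constant tensors so ops can mix both.
as_ag <- function(x) if (inherits(x, "ag_tensor")) x else new_ag(x, FALSE, list(), NULL)

ag_op <- function(value, parents, backward) {
  req <- FALSE
  for (p in parents) if (p$requires_grad) { req <- TRUE; break }
  if (!req) return(new_ag(value, FALSE, list(), NULL))
  new_ag(value, TRUE, parents, backward)
}

#' Run reverse-mode backpropagation from a scalar (or seeded) tensor
#'
#' @param root the output `ag_tensor`.
#' @param grad seed gradient; defaults to 1 (scalar outputs).
#' @export
ag_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  tag <- .ag_state$tag <- .ag_state$tag + 1L
  topo <- vector("list", 256L)
  nt <- 0L
  visit <- function(n) {
    if (identical(n$.tag, tag)) return(invisible())
    n$.tag <- tag
    if (n$requires_grad) for (p in n$parents) visit(p)
    nt <<- nt + 1L
    if (nt > length(topo)) length(topo) <<- 2L * nt
    topo[[nt]] <<- n
    invisible()
  }
  visit(root)
  root$grad <- grad
  for (i in seq(nt, 1L)) {
    n <- topo[[i]]
    if (is.null(n$backward_fn) || is.null(n$grad)) next
    gs <- n$backward_fn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$requires_grad) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (length(n$parents)) n$grad <- NULL # free interior gradients
  }
  invisible(root)
}

#' Zero the accumulated gradients of a list of tensors
#' @param params list of `ag_tensor`s.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

ag_value <- function(x) if (inherits(x, "ag_tensor")) x$value else x

# --- elementwise arithmetic -------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value * b$value, list(a, b), function(g) list(g * b$value, g * a$value))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value / b$value, list(a, b),
        function(g) list(g / b$value, -g * a$value / (b$value^2)))
}

ag_scale <- function(a, s) ag_op(a$value * s, list(a), function(g) list(g * s))

ag_square <- function(a) ag_op(a$value^2, list(a), function(g) list(2 * g * a$value))

ag_sqrt <- function(a) {
  y <- sqrt(a$value)
  ag_op(y, list(a), function(g) list(g * 0.5 / pmax(y, 1e-12)))
}

ag_exp <- function(a) {
  y <- exp(a$value)
  ag_op(y, list(a), function(g) list(g * y))
}

ag_log <- function(a) ag_op(log(a$value), list(a), function(g) list(g / a$value))

ag_pmax2 <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$value >= b$value
  ag_op(pmax(a$value, b$value), list(a, b),
        function(g) list(g * m, g * !m))
}

ag_pmin2 <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$value <= b$value
  ag_op(pmin(a$value, b$value), list(a, b),
        function(g) list(g * m, g * !m))
}

ag_clamp_min <- function(a, lo) {
  m <- a$value >= lo
  ag_op(pmax(a$value, lo), list(a), function(g) list(g * m))
}

# --- activations ------------------------------------------------------------

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(a) {
  r <- silu_fwd_cpp(a$value)
  ag_op(r$y, list(a), function(g) list(silu_bwd_cpp(g, a$value, r$s)))
}

ag_relu <- function(a) {
  m <- a$value > 0
  ag_op(a$value * m, list(a), function(g) list(g * m))
}

# Sigmoid-form GELU approximation x * sigmoid(1.702 x): one exponential per
# element instead of the Gaussian cdf/pdf pair.
ag_gelu <- function(a) {
  r <- gelu_fwd_cpp(a$value)
  ag_op(r$y, list(a), function(g) list(gelu_bwd_cpp(g, a$value, r$s)))
}

# --- reductions -------------------------------------------------------------

ag_sum <- function(a) {
  d <- dim(a$value)
  ag_op(sum(a$value), list(a), function(g) {
    out <- array(as.numeric(g), dim = if (is.null(d)) length(a$value) else d)
    list(out)
  })
}

ag_mean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  ag_op(mean(a$value), list(a), function(g) {
    out <- array(as.numeric(g) / n, dim = if (is.null(d)) n else d)
    list(out)
  })
}

# --- shape manipulation -----------------------------------------------------

ag_reshape <- function(a, dims) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ag_op(v, list(a), function(g) {
    dim(g) <- if (is.null(old)) NULL else old
    list(g)
  })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  ag_op(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# Concatenate 4-d arrays (H,W,C,N) along the channel axis.
ag_concat_c <- function(xs) {
  xs <- lapply(xs, as_ag)
  ds <- lapply(xs, function(x) dim(x$value))
  H <- ds[[1]][1]; W <- ds[[1]][2]; N <- ds[[1]][4]
  cs <- vapply(ds, function(d) d[3], numeric(1))
  Ct <- sum(cs)
  out <- array(0, dim = c(H, W, Ct, N))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  offs <- cumsum(c(0, cs))
  ag_op(out, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      gi <- g[, , offs[i] + seq_len(cs[i]), , drop = FALSE]
      dim(gi) <- ds[[i]]
      gi
    })
  })
}

# Gather arbitrary flat indices; backward scatter-adds (duplicates allowed).
ag_gather <- function(a, idx, out_dim = NULL) {
  v <- a$value[idx]
  if (!is.null(out_dim)) dim(v) <- out_dim
  n <- length(a$value)
  d <- dim(a$value)
  ag_op(v, list(a), function(g) {
    dx <- scatter_add_cpp(n, as.integer(idx), as.numeric(g))
    if (!is.null(d)) dim(dx) <- d
    list(dx)
  })
}

# Zero-pad a (H,W,C,N) map at the bottom/right; backward crops.
ag_pad_hw <- function(a, pb, pr) {
  d <- dim(a$value)
  if (pb == 0 && pr == 0) return(a)
  out <- array(0, dim = c(d[1] + pb, d[2] + pr, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- a$value
  ag_op(out, list(a), function(g) {
    gi <- g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
    dim(gi) <- d
    list(gi)
  })
}

ag_crop_hw <- function(a, h, w) {
  d <- dim(a$value)
  if (d[1] == h && d[2] == w) return(a)
  out <- a$value[seq_len(h), seq_len(w), , , drop = FALSE]
  ag_op(out, list(a), function(g) {
    dx <- array(0, dim = d)
    dx[seq_len(h), seq_len(w), , ] <- g
    list(dx)
  })
}

# Cyclic shift along H and W (positive = toward larger indices).
ag_roll_hw <- function(a, dh, dw) {
  d <- dim(a$value)
  ri <- if (dh == 0) seq_len(d[1]) else ((seq_len(d[1]) - 1 - dh) %% d[1]) + 1
  ci <- if (dw == 0) seq_len(d[2]) else ((seq_len(d[2]) - 1 - dw) %% d[2]) + 1
  out <- a$value[ri, ci, , , drop = FALSE]
  rb <- order(ri); cb <- order(ci)
  ag_op(out, list(a), function(g) list(g[rb, cb, , , drop = FALSE]))
}

# --- linear algebra ---------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

# x: (M, Cin) matrix; W: (Cin, Cout); b: length Cout or NULL.
ag_linear <- function(x, w, b = NULL) {
  y <- x$value %*% w$value
  if (!is.null(b)) y <- y + rep(b$value, each = nrow(y))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(y, parents, function(g) {
    out <- list(g %*% t(w$value), crossprod(x$value, g))
    if (!is.null(b)) out[[3]] <- colSums(g)
    out
  })
}

# Batched matrix multiply on cubes (m,k,B) via compiled kernel.
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_ag(a); b <- as_ag(b)
  y <- bmm_cpp(a$value, b$value, ta, tb)
  ag_op(y, list(a, b), function(g) {
    if (!ta && !tb) {
      da <- bmm_cpp(g, b$value, FALSE, TRUE)
      db <- bmm_cpp(a$value, g, TRUE, FALSE)
    } else if (ta && !tb) {
      da <- bmm_cpp(b$value, g, FALSE, TRUE)
      db <- bmm_cpp(a$value, g, FALSE, FALSE)
    } else if (!ta && tb) {
      da <- bmm_cpp(g, b$value, FALSE, FALSE)
      db <- bmm_cpp(g, a$value, TRUE, FALSE)
    } else {
      da <- bmm_cpp(b$value, g, TRUE, TRUE)
      db <- bmm_cpp(g, a$value, TRUE, TRUE)
    }
    list(da, db)
  })
}

# --- softmax over the first axis of a (K, M) matrix -------------------------

colmax_fast <- function(m) {
  # column maxima without apply(): pmax-reduce over rows
  Reduce(pmax, asplit(m, 1))
}

ag_softmax_dim1 <- function(a) {
  v <- a$value
  d <- dim(v)
  K <- d[1]
  m <- v
  dim(m) <- c(K, length(v) / K)
  mx <- colmax_fast(m)
  e <- exp(m - rep(mx, each = K))
  y <- e / rep(colSums(e), each = K)
  dim(y) <- d
  ag_op(y, list(a), function(g) {
    gm <- g; dim(gm) <- dim(m)
    ym <- y; dim(ym) <- dim(m)
    dx <- ym * (gm - rep(colSums(gm * ym), each = K))
    dim(dx) <- d
    list(dx)
  })
}

# --- normalization ----------------------------------------------------------

# Layer norm over rows of an (M, C) matrix (per-token over channels).
ag_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  r <- ln_fwd_cpp(x$value, gamma$value, beta$value, eps)
  ag_op(r$y, list(x, gamma, beta), function(g) {
    b <- ln_bwd_cpp(g, x$value, gamma$value, r$mu, r$inv)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# Batch norm over columns of an (M, C) matrix; `st` is an environment with
# running_mean / running_var / momentum / eps, `training` toggles stats.
ag_batchnorm_cols <- function(x, gamma, beta, st, training) {
  v <- x$value
  M <- nrow(v); C <- ncol(v)
  if (training) {
    mu <- colMeans(v)
    xc <- v - rep(mu, each = M)
    va <- colMeans(xc * xc)
    st$running_mean <- (1 - st$momentum) * st$running_mean + st$momentum * mu
    unb <- if (M > 1) M / (M - 1) else 1
    st$running_var <- (1 - st$momentum) * st$running_var + st$momentum * va * unb
  } else {
    mu <- st$running_mean
    xc <- v - rep(mu, each = M)
    va <- st$running_var
  }
  inv <- 1 / sqrt(va + st$eps)
  xh <- xc * rep(inv, each = M)
  y <- xh * rep(gamma$value, each = M) + rep(beta$value, each = M)
  ag_op(y, list(x, gamma, beta), function(g) {
    gr <- g * rep(gamma$value, each = M)
    if (training) {
      t1 <- colMeans(gr)
      t2 <- colMeans(gr * xh)
      dx <- rep(inv, each = M) * (gr - rep(t1, each = M) - xh * rep(t2, each = M))
    } else {
      dx <- gr * rep(inv, each = M)
    }
    list(dx, colSums(g * xh), colSums(g))
  })
}

# Fused batch norm on a (H,W,C,N) map, per-channel statistics over (H,W,N).
ag_batchnorm_hwcn <- function(x, gamma, beta, st, training) {
  d <- dim(x$value)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- HW * N
  r <- bn_fwd_cpp(x$value, HW, C, N, gamma$value, beta$value,
                  st$running_mean, st$running_var, training, st$eps)
  if (training) {
    st$running_mean <- (1 - st$momentum) * st$running_mean + st$momentum * r$mu
    unb <- if (M > 1) M / (M - 1) else 1
    st$running_var <- (1 - st$momentum) * st$running_var + st$momentum * r$va * unb
  }
  ag_op(r$y, list(x, gamma, beta), function(g) {
    b <- bn_bwd_cpp(g, x$value, HW, C, N, gamma$value, r$mu, r$va, training, st$eps)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# --- global average over H,W of a (H,W,C,N) map -> (C,N) matrix -------------

ag_mean_hw <- function(a) {
  d <- dim(a$value)
  HW <- d[1] * d[2]
  m <- a$value
  dim(m) <- c(HW, d[3] * d[4])
  y <- colMeans(m)
  dim(y) <- c(d[3], d[4])
  ag_op(y, list(a), function(g) {
    dx <- rep(as.numeric(g) / HW, each = HW)
    dim(dx) <- d
    list(dx)
  })
}

# Multiply a (H,W,C,N) map channel-wise by a (C,N) gate.
ag_mul_channel <- function(a, gate) {
  d <- dim(a$value)
  HW <- d[1] * d[2]
  gv <- rep(as.numeric(gate$value), each = HW)
  dim(gv) <- d
  y <- a$value * gv
  ag_op(y, list(a, gate), function(g) {
    dgm <- g * a$value
    dim(dgm) <- c(HW, d[3] * d[4])
    dg <- colSums(dgm)
    dim(dg) <- c(d[3], d[4])
    list(g * gv, dg)
  })
}

# Fused attention softmax: softmax(scale*scores + relposbias + mask) over the
# key axis, with the bias gathered from a learned table and its gradient
# scatter-added back.
ag_att_softmax <- function(scores, table, rp_idx, mask, scale, heads, T) {
  bias <- table$value[rp_idx]
  dim(bias) <- c(T, T, heads)
  y <- att_softmax_cpp(scores$value, bias, mask, scale, heads)
  ag_op(y, list(scores, table), function(g) {
    r <- att_softmax_bwd_cpp(g, y, scale, heads)
    dt <- scatter_add_cpp(length(table$value), rp_idx, as.numeric(r$dbias))
    dim(dt) <- dim(table$value)
    list(r$ds, dt)
  })
}

# --- fused binary-cross-entropy on logits -----------------------------------

# z: logits tensor; target, weight: plain arrays of the same shape.
# value = sum(weight * softplus-form BCE); backward is weight * (sigmoid(z)-t).
ag_bce_logits <- function(z, target, weight = NULL, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  v <- z$value
  t <- target
  l <- pmax(v, 0) - v * t + log1p(exp(-abs(v)))
  if (!is.null(weight)) l <- l * weight
  n <- if (reduction == "mean") length(v) else 1
  val <- sum(l) / n
  d <- dim(v)
  ag_op(val, list(z), function(g) {
    s <- 1 / (1 + exp(-v))
    dz <- (s - t)
    if (!is.null(weight)) dz <- dz * weight
    dz <- dz * (as.numeric(g) / n)
    if (!is.null(d)) dim(dz) <- d
    list(dz)
  })
}

# --- compiled-kernel wrappers ----------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L) {
  y <- conv2d_fwd_cpp(x$value, w$value, b$value, as.integer(stride))
  ag_op(y, list(x, w, b), function(g) {
    r <- conv2d_bwd_cpp(x$value, w$value, g, as.integer(stride), x$requires_grad)
    list(if (x$requires_grad) r$dx else NULL, r$dw, r$db)
  })
}

ag_maxpool <- function(x, k) {
  r <- maxpool_fwd_cpp(x$value, as.integer(k))
  n <- length(x$value)
  d <- dim(x$value)
  ag_op(r$y, list(x), function(g) {
    dx <- maxpool_bwd_cpp(as.numeric(g), r$idx, n)
    dim(dx) <- d
    list(dx)
  })
}

# Nearest-neighbour 2x spatial upsampling of a (H,W,C,N) map.
ag_upsample2 <- function(a) {
  d <- dim(a$value)
  ro <- rep(seq_len(d[1]), each = 2)
  co <- rep(seq_len(d[2]), each = 2)
  y <- a$value[ro, co, , , drop = FALSE]
  ag_op(y, list(a), function(g) {
    o1 <- seq(1, 2 * d[1], 2); o2 <- seq(2, 2 * d[1], 2)
    e1 <- seq(1, 2 * d[2], 2); e2 <- seq(2, 2 * d[2], 2)
    dx <- g[o1, e1, , , drop = FALSE] + g[o2, e1, , , drop = FALSE] +
      g[o1, e2, , , drop = FALSE] + g[o2, e2, , , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}
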