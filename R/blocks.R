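# ---------------------------------------------------------------------------
# Network building blocks.
#
# Feature maps flow through the graph as (H, W, C, N) arrays wrapped in
# autodiff tensors. "CBL" is convolution + batch norm + SiLU; CSP1/CSP2 are
# cross-stage-partial blocks (with / without residual units); SPP is
# spatial pyramid pooling; the Swin block is windowed multi-head
# self-attention with optional half-window cyclic shift; ConcatE is channel
# concatenation re-weighted by squeeze-and-excitation gates.
# ---------------------------------------------------------------------------

#' Space-to-depth slicing used by the Focus stem
#'
#' Splits an even-sized map into its four row/column parity subsamples and
#' stacks them along channels: (H, W, C) becomes (H/2, W/2, 4C). Every input
#' value appears exactly once in the output.
#'
#' @param x `ag_tensor` or array of dim (H, W, C, N) with H, W even.
#' @return tensor of dim (H/2, W/2, 4C, N).
#' @export
focus_slice <- function(x) {
  plain <- !inherits(x, "ag_tensor")
  x <- as_ag(x)
  d <- dim(x$value)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("focus_slice requires even spatial extent, got ", d[1], "x", d[2])
  }
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  h2 <- H / 2; w2 <- W / 2
  ho <- seq(1, H, 2); he <- seq(2, H, 2)
  wo <- seq(1, W, 2); we <- seq(2, W, 2)
  flat_idx <- function(ri, ci) {
    # flat indices of x[ri, ci, , ] in (H,W,C,N)
    base <- outer(ri, (ci - 1) * H, "+") # (h2, w2)
    cn <- (seq_len(C * N) - 1) * (H * W)
    idx <- outer(as.numeric(base), cn, "+")
    dim(idx) <- c(h2, w2, C, N)
    idx
  }
  parts <- list(flat_idx(ho, wo), flat_idx(he, wo), flat_idx(ho, we), flat_idx(he, we))
  slices <- lapply(parts, function(ix) ag_gather(x, as.integer(ix), c(h2, w2, C, N)))
  out <- ag_concat_c(slices)
  if (plain) out$value else out
}

nn_focus <- function(cin, cout, k = 3) {
  m <- nn_module("nn_focus")
  conv <- nn_child(m, "conv", nn_cbl(cin * 4, cout, k, 1))
  m$forward <- function(x, train = FALSE) conv$forward(focus_slice(x), train)
  m
}

# Plain convolution (no norm / activation), used inside CSP branches.
nn_conv_plain <- function(cin, cout, k = 1, stride = 1) {
  nn_cbl(cin, cout, k, stride, act = "none", bn = FALSE)
}

# Standalone BatchNorm + SiLU applied after the CSP branch concatenation.
nn_bnact <- function(c) {
  m <- nn_module("nn_bnact")
  gamma <- nn_param(m, "gamma", rep(1, c))
  beta <- nn_param(m, "beta", numeric(c))
  bnst <- new.env(parent = emptyenv())
  bnst$running_mean <- numeric(c)
  bnst$running_var <- rep(1, c)
  bnst$momentum <- 0.03
  bnst$eps <- 1e-3
  for (f in c("running_mean", "running_var")) {
    e <- new.env(parent = emptyenv()); e$st <- bnst; e$field <- f
    m$.buffers[[f]] <- e
  }
  m$forward <- function(x, train = FALSE) {
    ag_silu(ag_batchnorm_hwcn(x, gamma, beta, bnst, train))
  }
  m
}

# Residual unit: 1x1 CBL -> 3x3 CBL -> skip add.
nn_resunit <- function(c) {
  m <- nn_module("nn_resunit")
  cv1 <- nn_child(m, "cv1", nn_cbl(c, c, 1))
  cv2 <- nn_child(m, "cv2", nn_cbl(c, c, 3))
  m$forward <- function(x, train = FALSE) {
    ag_add(x, cv2$forward(cv1$forward(x, train), train))
  }
  m
}

# Cross-stage-partial block, residual variant (backbone).
nn_csp1 <- function(cin, cout, n) {
  stopifnot(n >= 1)
  m <- nn_module("nn_csp1")
  c_ <- max(cout %/% 2, 1)
  cv1 <- nn_child(m, "cv1", nn_cbl(cin, c_, 1))
  units <- lapply(seq_len(n), function(i) {
    nn_child(m, paste0("res", i), nn_resunit(c_))
  })
  mid <- nn_child(m, "mid", nn_conv_plain(c_, c_, 1))
  cv2 <- nn_child(m, "cv2", nn_conv_plain(cin, c_, 1))
  bnact <- nn_child(m, "bnact", nn_bnact(2 * c_))
  cv3 <- nn_child(m, "cv3", nn_cbl(2 * c_, cout, 1))
  m$forward <- function(x, train = FALSE) {
    y1 <- cv1$forward(x, train)
    for (u in units) y1 <- u$forward(y1, train)
    y1 <- mid$forward(y1, train)
    y2 <- cv2$forward(x, train)
    cv3$forward(bnact$forward(ag_concat_c(list(y1, y2)), train), train)
  }
  m
}

# CSP variant without residual skips (neck): each unit is a CBL pair.
nn_csp2 <- function(cin, cout, n) {
  stopifnot(n >= 1)
  m <- nn_module("nn_csp2")
  c_ <- max(cout %/% 2, 1)
  cv1 <- nn_child(m, "cv1", nn_cbl(cin, c_, 1))
  units <- lapply(seq_len(n), function(i) {
    u <- nn_module("nn_cblpair")
    a <- nn_child(u, "a", nn_cbl(c_, c_, 1))
    b <- nn_child(u, "b", nn_cbl(c_, c_, 3))
    u$forward <- function(x, train = FALSE) b$forward(a$forward(x, train), train)
    nn_child(m, paste0("unit", i), u)
  })
  mid <- nn_child(m, "mid", nn_conv_plain(c_, c_, 1))
  cv2 <- nn_child(m, "cv2", nn_conv_plain(cin, c_, 1))
  bnact <- nn_child(m, "bnact", nn_bnact(2 * c_))
  cv3 <- nn_child(m, "cv3", nn_cbl(2 * c_, cout, 1))
  m$forward <- function(x, train = FALSE) {
    y1 <- cv1$forward(x, train)
    for (u in units) y1 <- u$forward(y1, train)
    y1 <- mid$forward(y1, train)
    y2 <- cv2$forward(x, train)
    cv3$forward(bnact$forward(ag_concat_c(list(y1, y2)), train), train)
  }
  m
}

# Spatial pyramid pooling: 1x1 reduce, three parallel same-padded max pools
# (kernels 5 / 9 / 13, stride 1) concatenated with the identity, 1x1 expand.
nn_spp <- function(cin, cout, kernels = c(5, 9, 13)) {
  m <- nn_module("nn_spp")
  c_ <- cin %/% 2
  cv1 <- nn_child(m, "cv1", nn_cbl(cin, c_, 1))
  cv2 <- nn_child(m, "cv2", nn_cbl(c_ * (1 + length(kernels)), cout, 1))
  m$kernels <- kernels
  m$forward <- function(x, train = FALSE) {
    y <- cv1$forward(x, train)
    pooled <- c(list(y), lapply(kernels, function(k) ag_maxpool(y, k)))
    cv2$forward(ag_concat_c(pooled), train)
  }
  m
}

# --- Swin transformer block -------------------------------------------------

#' Swin block configuration
#'
#' @param dim channel count at the insertion point.
#' @param window window side in cells (effective window is `min(window, h, w)`).
#' @param heads attention head count; `dim` must be divisible by it.
#' @param mlp_ratio hidden width of the MLP as a multiple of `dim`.
#' @param shifted use the half-window cyclic shift with cross-region masking.
#' @return a `swin_config` list.
#' @export
swin_config <- function(dim, window = 7, heads = max(1L, dim %/% 32L),
                        mlp_ratio = 4, shifted = FALSE) {
  if (dim %% heads != 0) stop("dim (", dim, ") not divisible by heads (", heads, ")")
  structure(list(dim = dim, window = as.integer(window), heads = as.integer(heads),
                 mlp_ratio = mlp_ratio, shifted = isTRUE(shifted)),
            class = "swin_config")
}

# Window partition index bookkeeping for an (Hp, Wp) padded map.
swin_geometry <- function(Hp, Wp, win) {
  nh <- Hp %/% win
  nw <- Wp %/% win
  T <- win * win
  # token t (1-based) sits at window-local (row, col):
  rr <- ((seq_len(T) - 1) %% win) + 1
  cc <- ((seq_len(T) - 1) %/% win) + 1
  list(nh = nh, nw = nw, T = T, row = rr, col = cc)
}

# Relative position index (T x T) into a (2w-1)^2-row bias table.
relpos_index <- function(win) {
  T <- win * win
  rr <- ((seq_len(T) - 1) %% win)
  cc <- ((seq_len(T) - 1) %/% win)
  dr <- outer(rr, rr, "-") + (win - 1)
  dc <- outer(cc, cc, "-") + (win - 1)
  dr + (2 * win - 1) * dc + 1 # (T, T), 1-based
}

# Attention mask (0 / -1e9) per window for the shifted configuration:
# tokens originating from different pre-shift regions must not attend.
swin_shift_mask <- function(Hp, Wp, win, s) {
  region <- matrix(0L, Hp, Wp)
  hb <- list(seq_len(Hp - win), if (win - s > 0) Hp - win + seq_len(win - s) else integer(0),
             Hp - s + seq_len(s))
  wb <- list(seq_len(Wp - win), if (win - s > 0) Wp - win + seq_len(win - s) else integer(0),
             Wp - s + seq_len(s))
  id <- 0L
  for (hi in hb) for (wi in wb) {
    if (length(hi) && length(wi)) region[hi, wi] <- id
    id <- id + 1L
  }
  # region labels are defined on the post-roll canvas: after the cyclic shift
  # by -s the bottom/right bands hold wrapped content, which these slices mark
  # as distinct regions.
  nh <- Hp %/% win; nw <- Wp %/% win; T <- win * win
  mask <- array(0, dim = c(T, T, nh * nw))
  wi <- 0L
  for (cw in seq_len(nw)) for (rw in seq_len(nh)) {
    wi <- wi + 1L
    ids <- as.vector(region[(rw - 1) * win + seq_len(win), (cw - 1) * win + seq_len(win)])
    mask[, , wi] <- ifelse(outer(ids, ids, "!="), -1e9, 0)
  }
  mask
}

#' Build a Swin transformer block module
#'
#' Layer norm, (shifted-)window multi-head self-attention with a learned
#' relative position bias, residual add, layer norm, GELU MLP, residual add.
#' Shape-preserving; spatial extents not divisible by the window are
#' zero-padded and cropped back.
#'
#' @param cfg a [swin_config()].
#' @return a module; call `m$forward(x, train)` on a (H, W, dim, N) tensor.
#' @export
nn_swin_block <- function(cfg) {
  m <- nn_module("nn_swin")
  m$cfg <- cfg
  C <- cfg$dim
  hd_heads <- cfg$heads
  ln1g <- nn_param(m, "ln1.gamma", rep(1, C))
  ln1b <- nn_param(m, "ln1.beta", numeric(C))
  qkv <- nn_child(m, "qkv", nn_linear(C, 3 * C))
  proj <- nn_child(m, "proj", nn_linear(C, C))
  ln2g <- nn_param(m, "ln2.gamma", rep(1, C))
  ln2b <- nn_param(m, "ln2.beta", numeric(C))
  hidden <- round(C * cfg$mlp_ratio)
  fc1 <- nn_child(m, "fc1", nn_linear(C, hidden))
  fc2 <- nn_child(m, "fc2", nn_linear(hidden, C))
  # relative position bias table sized for the configured window; when the
  # effective window is smaller the central sub-table is used.
  nrel <- (2 * cfg$window - 1)^2
  rpb <- nn_param(m, "relpos", matrix(stats::rnorm(nrel * cfg$heads, 0, 0.02),
                                      nrel, cfg$heads))
  m$cache <- new.env(parent = emptyenv())

  m$forward <- function(x, train = FALSE) {
    d <- dim(x$value)
    H <- d[1]; W <- d[2]; N <- d[4]
    stopifnot(d[3] == C)
    win <- min(cfg$window, H, W)
    Hp <- ceiling(H / win) * win
    Wp <- ceiling(W / win) * win
    geo <- swin_geometry(Hp, Wp, win)
    T <- geo$T
    nwin <- geo$nh * geo$nw
    B <- nwin * N
    heads <- cfg$heads
    hd <- C %/% heads
    shift <- if (cfg$shifted && win > 1) win %/% 2 else 0L

    key <- paste(H, W, N, win, shift, sep = "_")
    cc <- m$cache[[key]]
    if (is.null(cc)) {
      cc <- list()
      M <- T * B
      # relative position bias gather index, expanded over heads
      ri <- relpos_index(win)
      if (win < cfg$window) {
        # map the small-window displacement onto the full-size table
        rr <- ((seq_len(T) - 1) %% win)
        ccol <- ((seq_len(T) - 1) %/% win)
        dr <- outer(rr, rr, "-") + (cfg$window - 1)
        dc <- outer(ccol, ccol, "-") + (cfg$window - 1)
        ri <- dr + (2 * cfg$window - 1) * dc + 1
      }
      idx <- as.numeric(ri)
      cc$rp_idx <- as.integer(outer(idx, (seq_len(heads) - 1) * nrel, "+"))
      # window partition as one flat gather (cyclic shift folded in):
      # token-matrix row m = t + T*(b-1), b = rw + nh*(cw-1) + nh*nw*(n-1)
      tseq <- seq_len(T); bseq <- seq_len(B)
      wr <- ((tseq - 1) %% win) + 1
      wc <- ((tseq - 1) %/% win) + 1
      rw <- ((bseq - 1) %% geo$nh) + 1
      cw <- (((bseq - 1) %/% geo$nh) %% geo$nw) + 1
      nn <- ((bseq - 1) %/% (geo$nh * geo$nw)) + 1
      h0 <- outer(wr, (rw - 1) * win, "+") # (T, B)
      w0 <- outer(wc, (cw - 1) * win, "+")
      if (shift > 0) {
        h0 <- ((h0 - 1 + shift) %% Hp) + 1
        w0 <- ((w0 - 1 + shift) %% Wp) + 1
      }
      nmat <- matrix(nn, T, B, byrow = TRUE)
      base <- h0 + Hp * (w0 - 1) # (T, B), channel/image strides added below
      pidx <- outer(as.numeric(base + Hp * Wp * C * (nmat - 1)),
                    Hp * Wp * (seq_len(C) - 1), "+")
      cc$part_idx <- as.integer(pidx) # (M, C)
      cc$part_inv <- order(cc$part_idx)
      # (M, 3C) -> per-q/k/v cubes (T, hd, heads*B)
      cube_idx <- function(offset) {
        t_ <- rep(tseq, times = hd * heads * B)
        d_ <- rep(rep(seq_len(hd), each = T), times = heads * B)
        hb <- rep(seq_len(heads * B), each = T * hd)
        h_ <- ((hb - 1) %% heads) + 1
        b_ <- ((hb - 1) %/% heads) + 1
        row <- t_ + T * (b_ - 1)
        col <- offset + d_ + hd * (h_ - 1)
        as.integer(row + M * (col - 1))
      }
      cc$q_idx <- cube_idx(0); cc$k_idx <- cube_idx(C); cc$v_idx <- cube_idx(2 * C)
      # attention output cube (T, hd, heads*B) -> token matrix (M, C)
      m_ <- seq_len(M)
      tm_ <- ((m_ - 1) %% T) + 1
      bm_ <- ((m_ - 1) %/% T) + 1
      dmat <- matrix(((seq_len(C) - 1) %% hd) + 1, M, C, byrow = TRUE)
      hmat <- matrix(((seq_len(C) - 1) %/% hd) + 1, M, C, byrow = TRUE)
      cc$out_idx <- as.integer(tm_ + T * ((dmat - 1) + hd * ((hmat - 1) + heads * (bm_ - 1))))
      if (shift > 0) {
        msk <- swin_shift_mask(Hp, Wp, win, shift) # (T, T, nwin)
        full <- aperm(array(msk, c(T, T, nwin, heads, N)), c(1, 2, 4, 3, 5))
        dim(full) <- c(T, T, heads * B)
        cc$mask <- full
      }
      m$cache[[key]] <- cc
    }

    y <- ag_pad_hw(x, Hp - H, Wp - W)
    tok0 <- ag_gather(y, cc$part_idx, c(T * B, C)) # (M, C)

    # --- attention ---
    tl <- ag_layernorm_rows(tok0, ln1g, ln1b)
    qkv_m <- qkv$forward(tl, train) # (M, 3C)
    qh <- ag_gather(qkv_m, cc$q_idx, c(T, hd, heads * B))
    kh <- ag_gather(qkv_m, cc$k_idx, c(T, hd, heads * B))
    vh <- ag_gather(qkv_m, cc$v_idx, c(T, hd, heads * B))
    scores <- ag_bmm(kh, qh, FALSE, TRUE) # (Tk, Tq, hB), unscaled
    attn <- ag_att_softmax(scores, rpb, cc$rp_idx,
                           if (shift > 0) cc$mask else numeric(0),
                           1 / sqrt(hd), heads, T)
    out <- ag_bmm(attn, vh, TRUE, FALSE) # (Tq, hd, heads*B)
    out <- ag_gather(out, cc$out_idx, c(T * B, C))
    out <- proj$forward(out, train)
    tok <- ag_add(tok0, out)

    # --- MLP ---
    tl2 <- ag_layernorm_rows(tok, ln2g, ln2b)
    mlp <- fc2$forward(ag_gelu(fc1$forward(tl2, train)), train)
    tok <- ag_add(tok, mlp)

    # --- reverse partition (exact inverse permutation, shift undone) ---
    y <- ag_gather(tok, cc$part_inv, c(Hp, Wp, C, N))
    ag_crop_hw(y, H, W)
  }
  m
}

#' Apply a Swin transformer block to a plain feature map
#'
#' Convenience functional wrapper around [nn_swin_block()] for
#' experimentation: builds a block with fresh weights and runs it once.
#'
#' @param x (H, W, C, N) array or (H, W, C) array (a batch axis is added).
#' @param cfg a [swin_config()].
#' @param block optionally a prebuilt module whose weights to use.
#' @return array of the same shape as `x`.
#' @export
swin_block <- function(x, cfg, block = NULL) {
  drop3 <- length(dim(x)) == 3
  if (drop3) dim(x) <- c(dim(x), 1)
  if (is.null(block)) block <- nn_swin_block(cfg)
  y <- block$forward(ag_tensor(x), train = FALSE)$value
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}

# --- ConcatE: SE-gated channel concatenation --------------------------------

#' Build an SE-gated concatenation (ConcatE) module
#'
#' Concatenates feature maps along channels, squeezes each channel by global
#' average pooling, passes the channel vector through a two-layer bottleneck
#' (reduction `r`, ReLU, expansion, sigmoid gate) and rescales the
#' concatenated channels by the resulting gates.
#'
#' @param c_total total channel count after concatenation.
#' @param r bottleneck reduction ratio.
#' @return a module; call `m$forward(list_of_tensors, train)`.
#' @export
nn_concat_e <- function(c_total, r = 16) {
  m <- nn_module("nn_concat_e")
  hidden <- max(4L, c_total %/% r)
  fc1 <- nn_child(m, "fc1", nn_linear(c_total, hidden))
  fc2 <- nn_child(m, "fc2", nn_linear(hidden, c_total))
  m$c_total <- c_total
  m$forward <- function(xs, train = FALSE) {
    if (inherits(xs, "ag_tensor")) xs <- list(xs)
    if (length(xs) >= 2) {
      hs <- vapply(xs, function(x) dim(x$value)[1], numeric(1))
      ws <- vapply(xs, function(x) dim(x$value)[2], numeric(1))
      if (length(unique(hs)) > 1 || length(unique(ws)) > 1) {
        stop("concat_e: spatial extents differ: ",
             paste(hs, ws, sep = "x", collapse = ", "))
      }
      x <- ag_concat_c(xs)
    } else {
      x <- xs[[1]]
    }
    stopifnot(dim(x$value)[3] == c_total)
    sq <- ag_mean_hw(x) # (C, N)
    z <- ag_aperm(sq, c(2, 1)) # (N, C)
    g <- ag_sigmoid(fc2$forward(ag_relu(fc1$forward(z, train)), train))
    gate <- ag_aperm(g, c(2, 1)) # (C, N)
    ag_mul_channel(x, gate)
  }
  m
}

#' Functional SE-gated concatenation
#'
#' @param xs list of (H, W, C_i, N) arrays with equal spatial extents.
#' @param r bottleneck reduction ratio.
#' @param module optional prebuilt [nn_concat_e()] whose weights to use.
#' @return (H, W, sum C_i, N) array.
#' @export
concat_e <- function(xs, r = 16, module = NULL) {
  stopifnot(length(xs) >= 2)
  xs <- lapply(xs, function(x) {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    ag_tensor(x)
  })
  ct <- sum(vapply(xs, function(x) dim(x$value)[3], numeric(1)))
  if (is.null(module)) module <- nn_concat_e(ct, r)
  module$forward(xs, train = FALSE)$value
}
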