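# Neural-network core for the multi-task detector: 1-D convolutions
# (im2col + GEMM), depthwise convolutions, batch normalization, swish
# activations, inverted-residual (MBConv) blocks, and Adam. Written against
# base BLAS; activations are (channels, length, batch) arrays.

.idx_cache <- new.env(parent = emptyenv())

conv_pad <- function(k) k %/% 2L

conv_out_len <- function(L, k, s) {
  (L + 2L * conv_pad(k) - k) %/% s + 1L
}

# Gather indices mapping a padded (C, Lp, B) array to the im2col matrix of
# shape (C*k, Lo*B); memoized on the geometry.
im2col_idx <- function(C, L, B, k, s) {
  key <- paste(C, L, B, k, s, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  p <- conv_pad(k)
  Lp <- L + 2L * p
  Lo <- conv_out_len(L, k, s)
  starts <- (seq_len(Lo) - 1L) * s            # 0-based start in padded axis
  P <- outer(seq_len(k), starts, "+")         # (k, Lo), 1-based positions
  A <- (as.vector(P) - 1L) * C                # j fastest, then l
  I1 <- as.vector(outer(seq_len(C), A, "+"))  # c fastest, then j, then l
  idx <- as.integer(outer(I1, (seq_len(B) - 1L) * C * Lp, "+"))
  out <- list(idx = idx, Lp = Lp, Lo = Lo, p = p)
  .idx_cache[[key]] <- out
  out
}

pad_input <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  xp[, p + seq_len(d[2]), ] <- x
  xp
}

conv1d_fwd <- function(x, W, stride) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W) / C
  if (k == 1 && stride == 1) {            # pointwise conv: plain GEMM
    xm <- x; dim(xm) <- c(C, L * B)
    y <- W %*% xm
    dim(y) <- c(nrow(W), L, B)
    return(list(y = y, cache = list(col = xm, pointwise = TRUE,
                                    C = C, L = L, B = B)))
  }
  g <- im2col_idx(C, L, B, k, stride)
  xp <- pad_input(x, g$p)
  col <- xp[g$idx]
  dim(col) <- c(C * k, g$Lo * B)
  y <- W %*% col
  dim(y) <- c(nrow(W), g$Lo, B)
  list(y = y, cache = list(col = col, g = g, C = C, L = L, B = B,
                           stride = stride, k = k, pointwise = FALSE))
}

conv1d_bwd <- function(dy, W, cache, need_dx = TRUE) {
  ca <- cache
  dym <- dy; dim(dym) <- c(nrow(W), length(dy) / nrow(W))
  dW <- tcrossprod(dym, ca$col)
  dx <- NULL
  if (need_dx) {
    if (ca$pointwise) {
      dx <- crossprod(W, dym)
      dim(dx) <- c(ca$C, ca$L, ca$B)
    } else {
      dcol <- crossprod(W, dym)
      rs <- rowsum(as.vector(dcol), ca$g$idx)
      dxp <- numeric(ca$C * ca$g$Lp * ca$B)
      dxp[as.integer(rownames(rs))] <- rs
      dim(dxp) <- c(ca$C, ca$g$Lp, ca$B)
      dx <- dxp[, ca$g$p + seq_len(ca$L), , drop = FALSE]
    }
  }
  list(dW = dW, dx = dx)
}

dwconv_fwd <- function(x, W, stride) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W)
  p <- conv_pad(k)
  Lo <- conv_out_len(L, k, stride)
  xp <- pad_input(x, p)
  y <- array(0, c(C, Lo, B))
  pos0 <- (seq_len(Lo) - 1L) * as.integer(stride)
  for (j in seq_len(k)) {
    y <- y + xp[, pos0 + j, , drop = FALSE] * W[, j]
  }
  list(y = y, cache = list(xp = xp, k = k, stride = stride, p = p, L = L,
                           Lo = Lo, C = C, B = B))
}

dwconv_bwd <- function(dy, W, cache) {
  ca <- cache
  pos0 <- (seq_len(ca$Lo) - 1L) * as.integer(ca$stride)
  dW <- matrix(0, ca$C, ca$k)
  dxp <- array(0, dim(ca$xp))
  for (j in seq_len(ca$k)) {
    xs <- ca$xp[, pos0 + j, , drop = FALSE]
    m <- dy * xs; dim(m) <- c(ca$C, length(m) / ca$C)
    dW[, j] <- rowSums(m)
    dxp[, pos0 + j, ] <- dxp[, pos0 + j, , drop = FALSE] + dy * W[, j]
  }
  dx <- dxp[, ca$p + seq_len(ca$L), , drop = FALSE]
  list(dW = dW, dx = dx)
}

bn_fwd <- function(x, prm, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, length(x) / C)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * ivar
  y <- prm$gamma * xhat + prm$beta
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, ivar = ivar, d = d, train = train))
}

bn_bwd <- function(dy, prm, cache) {
  d <- cache$d; C <- d[1]
  dym <- dy; dim(dym) <- c(C, length(dy) / C)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  N <- ncol(dym)
  if (cache$train) {
    dx <- (prm$gamma * cache$ivar / N) *
      (N * dym - dbeta - cache$xhat * dgamma)
  } else {
    dx <- prm$gamma * cache$ivar * dym
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

swish_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(s = s, x = x))
}

swish_bwd <- function(dy, cache) {
  dy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

glorot <- function(n_out, n_in, fan_k = 1) {
  sd <- sqrt(2 / (n_in * fan_k + n_out * fan_k))
  matrix(stats::rnorm(n_out * n_in * fan_k, 0, sd), n_out, n_in * fan_k)
}

new_bn <- function(C) {
  list(prm = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(mean = rep(0, C), var = rep(1, C)))
}

# ---- model assembly -------------------------------------------------------

# Expand the block schedule (with repeats) into a flat layer list.
expand_schedule <- function(spec) {
  layers <- list()
  cin <- spec$leads
  layers[[1]] <- list(type = "stem", cin = cin, cout = spec$stem$c,
                      k = spec$stem$k, stride = spec$stem$s)
  cin <- spec$stem$c
  for (blk in spec$blocks) {
    for (r in seq_len(blk$r)) {
      layers[[length(layers) + 1]] <-
        list(type = "mbconv", cin = cin, cout = blk$c, k = blk$k,
             stride = if (r == 1) blk$s else 1L, expand = blk$e)
      cin <- blk$c
    }
  }
  layers[[length(layers) + 1]] <- list(type = "head", cin = cin,
                                       cout = spec$embedding_dim)
  layers
}

init_backbone <- function(spec) {
  lapply(expand_schedule(spec), function(ly) {
    if (ly$type == "stem") {
      ly$W <- glorot(ly$cout, ly$cin, ly$k)
      ly$bn <- new_bn(ly$cout)
    } else if (ly$type == "mbconv") {
      mid <- ly$cin * ly$expand
      if (ly$expand != 1) {
        ly$W_e <- glorot(mid, ly$cin); ly$bn_e <- new_bn(mid)
      }
      ly$W_d <- matrix(stats::rnorm(mid * ly$k, 0, sqrt(1 / ly$k)), mid, ly$k)
      ly$bn_d <- new_bn(mid)
      ly$W_p <- glorot(ly$cout, mid); ly$bn_p <- new_bn(ly$cout)
    } else {                            # head
      ly$W <- glorot(ly$cout, ly$cin)
      ly$bn <- new_bn(ly$cout)
    }
    ly
  })
}

backbone_fwd <- function(layers, x, train) {
  tape <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "stem") {
      cv <- conv1d_fwd(x, ly$W, ly$stride)
      bn <- bn_fwd(cv$y, ly$bn$prm, ly$bn$state, train)
      layers[[i]]$bn$state <- bn$state
      sw <- swish_fwd(bn$y)
      x <- sw$y
      tape[[i]] <- list(cv = cv$cache, bn = bn$cache, sw = sw$cache)
    } else if (ly$type == "mbconv") {
      x_in <- x
      if (ly$expand != 1) {
        cv_e <- conv1d_fwd(x, ly$W_e, 1L)
        bn_e <- bn_fwd(cv_e$y, ly$bn_e$prm, ly$bn_e$state, train)
        layers[[i]]$bn_e$state <- bn_e$state
        sw_e <- swish_fwd(bn_e$y)
        h <- sw_e$y
        te <- list(cv = cv_e$cache, bn = bn_e$cache, sw = sw_e$cache)
      } else { h <- x; te <- NULL }
      cv_d <- dwconv_fwd(h, ly$W_d, ly$stride)
      bn_d <- bn_fwd(cv_d$y, ly$bn_d$prm, ly$bn_d$state, train)
      layers[[i]]$bn_d$state <- bn_d$state
      sw_d <- swish_fwd(bn_d$y)
      cv_p <- conv1d_fwd(sw_d$y, ly$W_p, 1L)
      bn_p <- bn_fwd(cv_p$y, ly$bn_p$prm, ly$bn_p$state, train)
      layers[[i]]$bn_p$state <- bn_p$state
      res <- ly$stride == 1L && ly$cin == ly$cout
      x <- if (res) bn_p$y + x_in else bn_p$y
      tape[[i]] <- list(e = te, cv_d = cv_d$cache, bn_d = bn_d$cache,
                        sw_d = sw_d$cache, cv_p = cv_p$cache,
                        bn_p = bn_p$cache, res = res)
    } else {                            # head
      cv <- conv1d_fwd(x, ly$W, 1L)
      bn <- bn_fwd(cv$y, ly$bn$prm, ly$bn$state, train)
      layers[[i]]$bn$state <- bn$state
      sw <- swish_fwd(bn$y)
      x <- sw$y
      tape[[i]] <- list(cv = cv$cache, bn = bn$cache, sw = sw$cache)
    }
  }
  # global average pool over length
  d <- dim(x)
  m <- aperm(x, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  emb <- matrix(rowMeans(m), d[1], d[3])
  list(layers = layers, emb = emb, tape = tape, feat_dim = d)
}

backbone_bwd <- function(layers, tape, feat_dim, demb) {
  # un-pool the average
  d <- feat_dim
  dxm <- matrix(rep(as.vector(demb) / d[2], d[2]), d[1] * d[3], d[2])
  dim(dxm) <- c(d[1], d[3], d[2])
  dx <- aperm(dxm, c(1, 3, 2))
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; tp <- tape[[i]]
    if (ly$type %in% c("stem", "head")) {
      dsw <- swish_bwd(dx, tp$sw)
      dbn <- bn_bwd(dsw, ly$bn$prm, tp$bn)
      cvb <- conv1d_bwd(dbn$dx, ly$W, tp$cv, need_dx = (i > 1))
      grads[[i]] <- list(W = cvb$dW,
                         bn = list(gamma = dbn$dgamma, beta = dbn$dbeta))
      dx <- cvb$dx
    } else {
      dtop <- dx
      dbn_p <- bn_bwd(dtop, ly$bn_p$prm, tp$bn_p)
      cvb_p <- conv1d_bwd(dbn_p$dx, ly$W_p, tp$cv_p)
      dsw_d <- swish_bwd(cvb_p$dx, tp$sw_d)
      dbn_d <- bn_bwd(dsw_d, ly$bn_d$prm, tp$bn_d)
      cvb_d <- dwconv_bwd(dbn_d$dx, ly$W_d, tp$cv_d)
      g <- list(W_p = cvb_p$dW,
                bn_p = list(gamma = dbn_p$dgamma, beta = dbn_p$dbeta),
                W_d = cvb_d$dW,
                bn_d = list(gamma = dbn_d$dgamma, beta = dbn_d$dbeta))
      if (ly$expand != 1) {
        dsw_e <- swish_bwd(cvb_d$dx, tp$e$sw)
        dbn_e <- bn_bwd(dsw_e, ly$bn_e$prm, tp$e$bn)
        cvb_e <- conv1d_bwd(dbn_e$dx, ly$W_e, tp$e$cv)
        g$W_e <- cvb_e$dW
        g$bn_e <- list(gamma = dbn_e$dgamma, beta = dbn_e$dbeta)
        dx <- cvb_e$dx
      } else {
        dx <- cvb_d$dx
      }
      if (tp$res) dx <- dx + dtop
      grads[[i]] <- g
    }
  }
  grads
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function() list(t = 0, m = list(), v = list())

# Flatten model parameters to a named list of numeric arrays for the
# optimizer; `set` writes updated values back.
collect_params <- function(model) {
  out <- list()
  for (i in seq_along(model$backbone)) {
    ly <- model$backbone[[i]]
    for (nm in intersect(c("W", "W_e", "W_d", "W_p"), names(ly)))
      out[[paste0("L", i, ".", nm)]] <- ly[[nm]]
    for (nm in intersect(c("bn", "bn_e", "bn_d", "bn_p"), names(ly))) {
      out[[paste0("L", i, ".", nm, ".gamma")]] <- ly[[nm]]$prm$gamma
      out[[paste0("L", i, ".", nm, ".beta")]] <- ly[[nm]]$prm$beta
    }
  }
  out[["head.W"]] <- model$head$W
  out[["head.b"]] <- model$head$b
  out
}

collect_grads <- function(grads, dhead) {
  out <- list()
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    for (nm in intersect(c("W", "W_e", "W_d", "W_p"), names(g)))
      out[[paste0("L", i, ".", nm)]] <- g[[nm]]
    for (nm in intersect(c("bn", "bn_e", "bn_d", "bn_p"), names(g))) {
      out[[paste0("L", i, ".", nm, ".gamma")]] <- g[[nm]]$gamma
      out[[paste0("L", i, ".", nm, ".beta")]] <- g[[nm]]$beta
    }
  }
  out[["head.W"]] <- dhead$dW
  out[["head.b"]] <- dhead$db
  out
}

assign_params <- function(model, prm) {
  for (i in seq_along(model$backbone)) {
    ly <- model$backbone[[i]]
    for (nm in intersect(c("W", "W_e", "W_d", "W_p"), names(ly)))
      model$backbone[[i]][[nm]] <- prm[[paste0("L", i, ".", nm)]]
    for (nm in intersect(c("bn", "bn_e", "bn_d", "bn_p"), names(ly))) {
      model$backbone[[i]][[nm]]$prm$gamma <-
        prm[[paste0("L", i, ".", nm, ".gamma")]]
      model$backbone[[i]][[nm]]$prm$beta <-
        prm[[paste0("L", i, ".", nm, ".beta")]]
    }
  }
  model$head$W <- prm[["head.W"]]
  model$head$b <- prm[["head.b"]]
  model
}

adam_step <- function(prm, grd, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(prm)) {
    g <- grd[[nm]]
    if (is.null(g)) next
    if (is.null(st$m[[nm]])) { st$m[[nm]] <- g * 0; st$v[[nm]] <- g * 0 }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    prm[[nm]] <- prm[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(prm = prm, st = st)
}
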