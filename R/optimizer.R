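# Stochastic optimizers over flat named lists of numeric arrays.
# NAdam (Nesterov-accelerated Adam) is the default training optimizer;
# plain Adam and SGD are available through optimizer_kind.

.opt_init <- function(params, kind, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- params[[nm]]
    if (!is.null(dim(p)) && is.null(dim(g))) dim(g) <- dim(p)
    if (is.null(dim(p)) && !is.null(dim(g))) g <- as.numeric(g)
    if (opt$kind == "sgd") {
      params[[nm]] <- p - opt$lr * g
      next
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    num <- if (opt$kind == "nadam") b1 * mhat + (1 - b1) * g / bc1
           else mhat
    params[[nm]] <- p - opt$lr * num / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
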