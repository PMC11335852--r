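# Shared fixtures: tiny synthetic worlds and a finite-difference gradient
# oracle used to verify the hand-derived backward passes.

tiny_table <- function(V = 10L, d = 5L, seed = 1L) {
  set.seed(seed)
  embedding_table(sprintf("t%02d", seq_len(V)),
                  matrix(rnorm(V * d), V, d))
}

# central finite differences over every parameter entry
numeric_gradient <- function(f, params, eps = 1e-6) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p * 0
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      pm <- params; pm[[nm]][i] <- p[i] - eps
      g[i] <- (f(pp) - f(pm)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# analytic gradients of the full caption->image loss for a given config
analytic_gradient <- function(params, cfg, E, cap_idx, Y) {
  gr <- groundlex:::.ground_forward(params, cfg, E)
  fw <- groundlex:::.encoder_forward(params, cfg, cap_idx, gr$G)
  dpred <- 2 * (fw$pred - Y) / length(Y)
  bk <- groundlex:::.encoder_backward(params, cfg, fw$cache, dpred, nrow(E))
  c(bk$grads, groundlex:::.ground_backward(params, cfg, gr, bk$dGv))
}

encoder_loss_fn <- function(cfg, E, cap_idx, Y) {
  function(params) {
    gr <- groundlex:::.ground_forward(params, cfg, E)
    fw <- groundlex:::.encoder_forward(params, cfg, cap_idx, gr$G)
    mean((fw$pred - Y)^2)
  }
}
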