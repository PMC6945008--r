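# independent dense-grid oracle for the constrained index-pair optimum:
# sweeps both index angles on a dense circle grid through the public
# per-process response interface, refines the constraint root in t2 for
# every bracketing cell, and returns the best cumulated mixture response
# found on the constraint manifold
sgma_torus_oracle <- function(params, design, target, n_angles = 721) {
  tg <- seq(-pi, pi, length.out = n_angles)
  k1 <- target[1]
  k2 <- target[2]
  eval_proc <- function(t, focal) {
    r <- sgma_process_responses(params, design, c(cos(t), sin(t)), focal)
    # constraint piece in species terms; dG_x1/dG_x2 are already mapped
    c(f = r$dG_total, c = r$dG_x1 * k2 - r$dG_x2 * k1)
  }
  g1 <- vapply(tg, eval_proc, numeric(2), focal = 1)
  g2 <- vapply(tg, eval_proc, numeric(2), focal = 2)
  f1 <- g1["f", ]; c1 <- g1["c", ]
  f2 <- g2["f", ]; c2 <- g2["c", ]
  n <- length(tg)
  best <- -Inf
  f2max <- max(f2)
  cons <- function(t2, c1v) c1v + eval_proc(t2, 2)["c"]
  for (j in seq_len(n)) {
    if (f1[j] + f2max <= best) next  # cannot beat the incumbent
    h <- c1[j] + c2
    exact <- which(h == 0)
    for (e in exact) best <- max(best, f1[j] + f2[e])
    for (b in which(h[-n] * h[-1] < 0)) {
      root <- stats::uniroot(cons, c1v = c1[j],
                             lower = tg[b], upper = tg[b + 1],
                             tol = 1e-10)$root
      best <- max(best, f1[j] + eval_proc(root, 2)["f"])
    }
  }
  unname(best)
}
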