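# Shared fixtures built in code.

# fine-grid trapezoid quadrature oracle for Ka, independent of the package's
# integration path
ka_quadrature_oracle <- function(E_fun, R_U, T = 300, n = 200001L) {
  r <- seq(1e-6, R_U, length.out = n)
  g <- exp(-E_fun(r) / (8.314462e-3 * T))
  y <- 4 * pi * r^2 * g
  h <- r[2] - r[1]
  h * (sum(y) - (y[1] + y[n]) / 2)
}

# brute-force connected components by breadth-first search on an explicit
# contact graph (unit positions, symmetric cutoff matrix lookup)
bfs_cluster_oracle <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# minimum-image distance between two points (test-side re-implementation)
mic_dist_oracle <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# random ion frame of single-atom Ca/Oc ions for cluster property tests
random_ion_frame <- function(n, box_edge = 3, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, box_edge), ncol = 3)
  sp <- sample(c("Ca", "Oc"), n, replace = TRUE)
  traj_frame(pos, sp, rep(box_edge, 3))
}
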