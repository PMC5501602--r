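# Independent oracles used across the suite. These deliberately use different
# algorithms from the package implementations they check.

# Mann-Whitney AUC: Pr(tau_pos > tau_neg) + 0.5 Pr(tie), by explicit pairing.
mw_auc_oracle <- function(tau, labels) {
  pos <- tau[as.logical(labels)]
  neg <- tau[!as.logical(labels)]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Exhaustive threshold enumeration: for every candidate threshold compute
# (TPR, FPR) directly and return the sweep (used against roc_curve()).
roc_enumeration_oracle <- function(tau, labels) {
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  ts <- sort(unique(tau), decreasing = TRUE)
  do.call(rbind, lapply(ts, function(t) {
    pred <- tau >= t
    data.frame(threshold = t, TPR = sum(pred & labels) / P,
               FPR = sum(pred & !labels) / N)
  }))
}

# Brute-force flood-fill component labeling (BFS over an explicit queue).
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, d)
  lab <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- lab
      queue <- c(queue, new)
    }
  }
  labels
}

# two labelings agree up to renaming of labels
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- a > 0L
  key <- paste(a[fg], b[fg])
  length(unique(key)) == max(a) && max(a) == max(b)
}

# directly constructed truncated 3^3 Gaussian kernel (support 1)
gauss_kernel3_oracle <- function(sigma) {
  off <- -1:1
  k <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (l in 1:3)
    k[i, j, l] <- exp(-(off[i]^2 + off[j]^2 + off[l]^2) / (2 * sigma^2))
  k / sum(k)
}

# a hand-built uniform-velocity "solution" for stress-operator identities
uniform_flow_solution <- function(grid, u_const = 0, w_const = 1e-3) {
  structure(list(
    U = matrix(u_const, grid$nr + 1L, grid$nz),
    W = matrix(w_const, grid$nr, grid$nz + 1L),
    P = matrix(0, grid$nr, grid$nz),
    grid = grid, bc = flow_bc(v = w_const, tube_radius = grid$geom$tube_radius),
    fluid = fluid_props(), porous = porous_props(),
    diagnostics = list(), converged = TRUE), class = "flow_solution")
}
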