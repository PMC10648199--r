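# shared helpers: handcrafted PDB text, random rigid motions, and the
# brute-force rotational-search RMSD oracle used to validate the closed-form
# superposition

# minimal PDB writer for handcrafted fixtures: residues is a list of
# lists(resno, resname, atoms = named list of xyz), chain a single letter.
# Atoms may be omitted to simulate unresolved backbone atoms; an `alt`
# and `occ` entry produce altloc records.
write_fixture_pdb <- function(residues, path, chain = "A") {
  lines <- character(0)
  serial <- 0
  for (r in residues) {
    for (at in names(r$atoms)) {
      a <- r$atoms[[at]]
      alt <- if (!is.null(a$alt)) a$alt else " "
      occ <- if (!is.null(a$occ)) a$occ else 1
      xyz <- a$xyz
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, paste0(" ", at), alt, r$resname, chain, r$resno,
        xyz[1], xyz[2], xyz[3], occ, 0, substr(at, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# n fully resolved ALA residues along a synthetic helix backbone
helix_residues <- function(n, resno = seq_len(n)) {
  X <- pblocks:::nerf_chain(rep(-57, n), rep(-47, n))
  lapply(seq_len(n), function(i) {
    list(resno = resno[i], resname = "ALA", atoms = list(
      N = list(xyz = X[3 * i - 2, ]),
      CA = list(xyz = X[3 * i - 1, ]),
      C = list(xyz = X[3 * i, ])
    ))
  })
}

random_rotation <- function() {
  # QR-based uniform-ish random proper rotation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
  Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

# brute-force minimum RMSD over rotations: exhaustive Euler-angle grid
# followed by local refinement; independent of the SVD path.  The grid of
# flattened rotation matrices is shared across calls, and the cost of every
# rotation R is evaluated at once through the trace identity
#   ||Pc R - Qc||^2 = |Pc|^2 + |Qc|^2 - 2 tr(R^T H),  H = Pc^T Qc.
.oracle_env <- new.env()
rotation_grid <- function(step_deg = 6) {
  key <- paste0("grid", step_deg)
  if (is.null(.oracle_env[[key]])) {
    step <- step_deg * pi / 180
    ang <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                       b = seq(0, pi, by = step),
                       g = seq(0, 2 * pi - step, by = step))
    G <- matrix(0, nrow(ang), 9)
    for (i in seq_len(nrow(ang))) {
      G[i, ] <- as.vector(euler_rotation(ang$a[i], ang$b[i], ang$g[i]))
    }
    .oracle_env[[key]] <- list(G = G, ang = as.matrix(ang))
  }
  .oracle_env[[key]]
}

grid_rmsd_oracle <- function(P, Q, step_deg = 6, n_starts = 5) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)
  nP <- sum(Pc^2) + sum(Qc^2)
  grid <- rotation_grid(step_deg)
  cost <- as.vector(grid$G %*% as.vector(H))  # tr(R^T H) for every grid point
  starts <- grid$ang[order(cost, decreasing = TRUE)[seq_len(n_starts)], ,
                     drop = FALSE]
  tr_cost <- function(ang) sum(euler_rotation(ang[1], ang[2], ang[3]) * H)
  best <- max(cost)
  for (s in seq_len(nrow(starts))) {
    ref <- optim(starts[s, ], function(ang) -tr_cost(ang),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    best <- max(best, -ref$value)
  }
  sqrt(max(0, (nP - 2 * best) / nrow(P)))
}

# direct nested-model partial F: ((RSS0 - RSS1)/1) / (RSS1/(n - p - 1))
# where the larger model has p predictors (including the tested one)
partial_f_oracle <- function(X, y, feature, others) {
  d0 <- if (length(others) > 0) as.data.frame(X[, others, drop = FALSE]) else
    data.frame(row.names = seq_along(y))
  d1 <- as.data.frame(X[, c(others, feature), drop = FALSE])
  rss0 <- sum(residuals(lm(y ~ ., data = cbind(d0, y = y)))^2)
  f1 <- lm(y ~ ., data = cbind(d1, y = y))
  rss1 <- sum(residuals(f1)^2)
  p <- length(others) + 1
  ((rss0 - rss1) / 1) / (rss1 / (length(y) - p - 1))
}

pb_letters <- letters[1:16]
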