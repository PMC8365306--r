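# Quasi-static volume conduction: P1 finite-element assembly of the Poisson
# problem  div(sigma grad V) = -i  with pure Neumann boundary (insulating
# head boundary), solved by Jacobi-preconditioned conjugate gradient to a
# relative residual of 1e-8. The pure-Neumann operator is singular up to an
# additive constant; the gauge is fixed to zero mean. Units: mm, S/m, mA,
# giving voltages directly in volts.

#' Head-model conductivities (S/m)
#'
#' Isotropic literature conductivities per compartment: gray matter 0.330,
#' white matter 0.142, ventricles and CSF 1.790, silicone insulating sheet
#' 1e-10.
#'
#' @param ... overrides, e.g. `gray = 0.4`.
#' @return named numeric vector.
#' @export
conductivity_table <- function(...) {
  tab <- c(gray = 0.330, white = 0.142, ventricles = 1.790, csf = 1.790,
           silicone = 1e-10)
  over <- c(...)
  if (length(over)) tab[names(over)] <- over
  if (any(tab <= 0)) stop("conductivities must be positive", call. = FALSE)
  tab
}

#' Assemble the P1 stiffness operator
#'
#' Linear tetrahedral stiffness matrix for `div(sigma grad V)`; symmetric,
#' with zero row sums (the constant vector spans the pure-Neumann null
#' space).
#'
#' @param mesh a [tet_mesh()].
#' @param sigma named conductivity vector covering every region tag of the
#'   mesh (see [conductivity_table()]).
#' @return a sparse symmetric `dgCMatrix` (n_nodes x n_nodes).
#' @export
assemble <- function(mesh, sigma) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(sigma))
  if (length(missing))
    stop("no conductivity for region tag(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  t <- mesh$tets
  n <- mesh$nodes
  v1 <- n[t[, 1], , drop = FALSE]
  c1 <- n[t[, 2], , drop = FALSE] - v1
  c2 <- n[t[, 3], , drop = FALSE] - v1
  c3 <- n[t[, 4], , drop = FALSE] - v1
  cr23 <- row_cross(c2, c3)
  det <- row_dot(c1, cr23)               # 6 * volume
  if (any(det <= 0)) stop("assembly error: non-positive tet volume", call. = FALSE)
  g2 <- cr23 / det
  g3 <- row_cross(c3, c1) / det
  g4 <- row_cross(c1, c2) / det
  g1 <- -(g2 + g3 + g4)
  vol_sigma <- (det / 6) * as.numeric(sigma[mesh$region])
  G <- list(g1, g2, g3, g4)
  m <- nrow(t)
  nt <- 16L * m
  ii <- integer(nt); jj <- integer(nt); xx <- numeric(nt)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- pos + seq_len(m)
    ii[idx] <- t[, a]
    jj[idx] <- t[, b]
    xx[idx] <- vol_sigma * row_dot(G[[a]], G[[b]])
    pos <- pos + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(n), nrow(n)), repr = "C")
}

#' Bipolar stimulation configuration
#'
#' @param cathode,anode contact labels (must differ).
#' @param amplitude_mA stimulation amplitude I0 (mA, > 0).
#' @param phase_width_ms pulse phase width (default 1.2 ms).
#' @return an object of class `stim_config`.
#' @export
stim_config <- function(cathode, anode, amplitude_mA, phase_width_ms = 1.2) {
  if (identical(cathode, anode)) stop("cathode and anode must differ", call. = FALSE)
  if (amplitude_mA <= 0) stop("amplitude must be positive", call. = FALSE)
  structure(list(cathode = cathode, anode = anode,
                 amplitude_mA = amplitude_mA, phase_width_ms = phase_width_ms),
            class = "stim_config")
}

#' Load vector for bipolar stimulation
#'
#' `+I0` is spread over the anode disk's node weights and `-I0` over the
#' cathode's, so entries sum to zero (compatibility of the pure-Neumann
#' problem). The current is distributed uniformly over the 73 disk nodes
#' via their barycentric embedding rather than as a single-node delta,
#' which keeps the sampled self-voltage mesh-independent; a single-node
#' mode is available through [point_source_rhs()].
#'
#' @param mesh a [tet_mesh()] with embedded electrodes.
#' @param stim a [stim_config()].
#' @return numeric load vector (mA).
#' @export
make_rhs <- function(mesh, stim) {
  W <- mesh$electrode_weights
  if (is.null(W)) stop("mesh has no embedded electrodes", call. = FALSE)
  for (lab in c(stim$cathode, stim$anode)) {
    if (!lab %in% rownames(W))
      stop("unknown electrode label: ", lab, call. = FALSE)
  }
  as.numeric(stim$amplitude_mA * (W[stim$anode, ] - W[stim$cathode, ]))
}

#' Single-node point sources
#'
#' Places `+-I0` on the mesh nodes nearest to the given positions: the
#' discrete delta-source used by the analytic verification tests.
#'
#' @param mesh a [tet_mesh()].
#' @param source_pos,sink_pos length-3 positions (mm).
#' @param amplitude_mA current (mA).
#' @return numeric load vector (mA) summing to zero.
#' @export
point_source_rhs <- function(mesh, source_pos, sink_pos, amplitude_mA) {
  i1 <- nearest_node(mesh, source_pos)
  i2 <- nearest_node(mesh, sink_pos)
  if (i1 == i2) stop("source and sink coincide on the mesh", call. = FALSE)
  rhs <- numeric(nrow(mesh$nodes))
  rhs[i1] <- amplitude_mA
  rhs[i2] <- -amplitude_mA
  rhs
}

#' Nearest mesh node to a point
#' @param mesh a [tet_mesh()].
#' @param p length-3 position (mm).
#' @return node index.
#' @export
nearest_node <- function(mesh, p) {
  which.min((mesh$nodes[, 1] - p[1])^2 + (mesh$nodes[, 2] - p[2])^2 +
              (mesh$nodes[, 3] - p[3])^2)
}

#' Solve the volume-conduction system
#'
#' Jacobi-preconditioned conjugate gradient on the singular pure-Neumann
#' operator, with iterates deflated against the constant null space; the
#' returned solution has zero mean (the gauge).
#'
#' @param K stiffness operator from [assemble()].
#' @param rhs load vector; must sum to zero within round-off.
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @return a `nodal_solution`: list with `v` (volts), `residual` (relative),
#'   `iterations`, `gauge = "zero-mean"`.
#' @export
solve_fem <- function(K, rhs, tol = 1e-8, max_iter = 50000L) {
  n <- length(rhs)
  stopifnot(nrow(K) == n)
  scale <- max(abs(rhs))
  if (scale == 0) {
    return(structure(list(v = numeric(n), residual = 0, iterations = 0L,
                          gauge = "zero-mean"), class = "nodal_solution"))
  }
  if (abs(sum(rhs)) > 1e-9 * sum(abs(rhs)))
    stop("incompatible load: source currents must sum to zero", call. = FALSE)
  d <- Matrix::diag(K)
  d[d <= 0] <- min(d[d > 0])
  minv <- 1 / d
  proj <- function(v) v - mean(v)
  b <- proj(rhs)
  x <- numeric(n)
  r <- b
  z <- proj(minv * r)
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  res <- 1
  it <- 0L
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) break
    z <- proj(minv * r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (res > tol)
    stop(sprintf(
      "conjugate gradient did not reach tol %.1e in %d iterations (residual %.2e)",
      tol, max_iter, res), call. = FALSE)
  structure(list(v = proj(x), residual = res, iterations = it,
                 gauge = "zero-mean"), class = "nodal_solution")
}

#' @export
print.nodal_solution <- function(x, ...) {
  cat(sprintf("<nodal_solution: %d nodes, residual %.2e, %d CG iterations>\n",
              length(x$v), x$residual, x$iterations))
  invisible(x)
}

#' Simulated voltage at an electrode
#'
#' Mean of the nodal solution interpolated at the contact's 73 disk nodes
#' (through the same barycentric weights that spread the injected current).
#'
#' @param solution a `nodal_solution` from [solve_fem()].
#' @param mesh the [tet_mesh()] the solution was computed on.
#' @param label contact label, or a vector of labels.
#' @return voltage(s) in volts, named by label.
#' @export
electrode_voltage <- function(solution, mesh, label) {
  W <- mesh$electrode_weights
  if (is.null(W)) stop("mesh has no embedded electrodes", call. = FALSE)
  bad <- setdiff(label, rownames(W))
  if (length(bad)) stop("unknown electrode label: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  v <- as.numeric(W[label, , drop = FALSE] %*% solution$v)
  names(v) <- label
  v
}

#' Analytic half-space solution for a bipolar pair
#'
#' Image-charge solution for point monopoles on the insulating boundary of
#' a homogeneous half-space: `V(x) = I / (2 pi sigma) * (1/r+ - 1/r-)`.
#' Serves as the independent oracle for the FEM solver.
#'
#' @param I_mA current (mA).
#' @param sigma conductivity (S/m).
#' @param source_pos,sink_pos monopole positions on the boundary plane (mm);
#'   pass `sink_pos = NULL` for a single monopole.
#' @param query_points k x 3 points on or below the boundary (mm).
#' @return voltages (volts).
#' @export
analytic_half_space <- function(I_mA, sigma, source_pos, sink_pos,
                                query_points) {
  q <- rbind(query_points)
  rp <- sqrt(rowSums(sweep(q, 2, source_pos)^2))
  if (any(rp < 1e-9)) stop("query point coincides with the source", call. = FALSE)
  v <- I_mA / (2 * pi * sigma) / rp
  if (!is.null(sink_pos)) {
    rm <- sqrt(rowSums(sweep(q, 2, sink_pos)^2))
    if (any(rm < 1e-9)) stop("query point coincides with the sink", call. = FALSE)
    v <- v - I_mA / (2 * pi * sigma) / rm
  }
  v   # mA / (S/m * mm) is volts: 1e-3 A / (1e-3 S) = V
}
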