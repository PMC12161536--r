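#' Voxel tissue grid
#'
#' Regular 3D grid of tissue labels with per-tissue conductivities. Labels:
#' 0 air, 1 fat/skin, 2 muscle, 3 cortical bone, 4 cancellous bone. The
#' label stored at grid point (i, j, k) is read as the dominant tissue of
#' the voxel whose lower corner is that point. Air has zero conductivity and
#' is excluded from the finite-element solve domain; skin-air faces receive
#' the natural no-flux boundary condition.
#'
#' @param x,y,z strictly increasing axis coordinate vectors (mm).
#' @param labels integer array `length(x) x length(y) x length(z)` of tissue
#'   codes 0-4.
#' @param conductivity named vector (S/m) with entries `air`, `fat_skin`,
#'   `muscle`, `cortical_bone`, `cancellous_bone`.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(x, y, z, labels, conductivity) {
  stopifnot(all(diff(x) > 0), all(diff(y) > 0), all(diff(z) > 0),
            identical(dim(labels), c(length(x), length(y), length(z))))
  need <- c("air", "fat_skin", "muscle", "cortical_bone", "cancellous_bone")
  if (!all(need %in% names(conductivity)))
    stop("conductivity must name all five tissue classes")
  if (conductivity[["air"]] != 0) stop("air conductivity must be 0")
  if (!all(labels %in% 0:4)) stop("labels must be tissue codes 0..4")
  structure(list(x = x, y = y, z = z, labels = labels,
                 sigma = unname(conductivity[need])),  # indexed by label + 1
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d nodes, %.0f%% non-air\n",
              length(x$x), length(x$y), length(x$z),
              100 * mean(x$labels != 0L)))
  invisible(x)
}

# nearest-node indices for points (n x 3, mm), clamped into the grid
grid_nearest_node <- function(grid, pts) {
  snap <- function(ax, v) pmin(pmax(round((v - ax[1]) / (ax[2] - ax[1])) + 1, 1),
                               length(ax))
  cbind(i = snap(grid$x, pts[, 1]), j = snap(grid$y, pts[, 2]),
        k = snap(grid$z, pts[, 3]))
}

grid_label_at <- function(grid, pts) {
  idx <- grid_nearest_node(grid, pts)
  grid$labels[idx]
}

#' Place a cylindrical electrode grid on the skin surface
#'
#' Builds an M x N grid in cylindrical coordinates (M divisions in theta, N
#' in z) on a reference cylinder of radius `R` larger than the body, then
#' casts each electrode's segment toward the section centroid and snaps the
#' electrode to the first intersection with the tissue surface (first
#' non-air sample along the ray). The grid is centered axially at the
#' `z_center` fraction of the z-axis; z spacing is `spacing` mm and theta
#' spacing corresponds to `spacing` of arc at the outermost tissue radius.
#' The default montage pairs z-neighbors within each theta column as bipolar
#' channels.
#'
#' @param grid a [volume_grid()].
#' @param M,N theta and z divisions.
#' @param R reference cylinder radius (mm); must exceed the body's maximal
#'   radial extent.
#' @param z_center fraction of the z-extent at which the grid is centered.
#' @param spacing inter-electrode distance (mm).
#' @param theta_center azimuth of the grid center (radians).
#' @return object of class `electrode_array`: `positions` (n x 3 mm, ordered
#'   z-fastest within each theta column), `theta`, `z_nominal`, `bipolar`
#'   (pairs matrix), `M`, `N`.
#' @export
place_electrodes <- function(grid, M = 2L, N = 3L, R = 60, z_center = 0.3,
                             spacing = 15, theta_center = pi / 2) {
  body_r <- {
    nz <- which(grid$labels != 0L, arr.ind = TRUE)
    max(sqrt(grid$x[nz[, 1]]^2 + grid$y[nz[, 2]]^2))
  }
  if (R <= body_r) stop("reference cylinder radius must exceed the body")
  zc <- grid$z[1] + z_center * diff(range(grid$z))
  zs <- zc + (seq_len(N) - (N + 1) / 2) * spacing
  dth <- spacing / body_r
  ths <- theta_center + (seq_len(M) - (M + 1) / 2) * dth
  step <- min(grid$x[2] - grid$x[1], grid$y[2] - grid$y[1]) / 4
  pos <- matrix(NA_real_, M * N, 3, dimnames = list(NULL, c("x", "y", "z")))
  theta <- numeric(M * N); z_nom <- numeric(M * N)
  e <- 0L
  for (m in seq_len(M)) for (n in seq_len(N)) {
    e <- e + 1L
    start <- c(R * cos(ths[m]), R * sin(ths[m]), zs[n])
    target <- c(0, 0, zs[n])  # section centroid on the axis
    L <- sqrt(sum((target - start)^2))
    tt <- seq(0, 1, by = step / L)
    ray <- cbind(start[1] + tt * (target[1] - start[1]),
                 start[2] + tt * (target[2] - start[2]),
                 start[3] + tt * (target[3] - start[3]))
    inside <- ray[, 1] >= grid$x[1] & ray[, 1] <= grid$x[length(grid$x)] &
      ray[, 2] >= grid$y[1] & ray[, 2] <= grid$y[length(grid$y)] &
      ray[, 3] >= grid$z[1] & ray[, 3] <= grid$z[length(grid$z)]
    hit <- which(inside & grid_label_at(grid, ray) != 0L)[1]
    if (is.na(hit)) stop(sprintf("electrode ray %d misses the body", e))
    # bisection between the last air sample and the first tissue sample
    # pins the electrode to the surface
    if (hit > 1L) {
      t_lo <- tt[hit - 1L]; t_hi <- tt[hit]
      for (it in 1:40) {
        t_mid <- (t_lo + t_hi) / 2
        pm <- start + t_mid * (target - start)
        if (grid_label_at(grid, matrix(pm, 1)) != 0L) t_hi <- t_mid
        else t_lo <- t_mid
      }
      pos[e, ] <- start + t_hi * (target - start)
    } else pos[e, ] <- ray[hit, ]
    theta[e] <- ths[m]; z_nom[e] <- zs[n]
  }
  # bipolar montage: consecutive z neighbors within each theta column
  bip <- do.call(rbind, lapply(seq_len(M), function(m) {
    base <- (m - 1L) * N
    if (N < 2L) NULL else cbind(base + seq_len(N - 1L), base + 2:N)
  }))
  structure(list(positions = pos, theta = theta, z_nominal = z_nom,
                 bipolar = bip, M = M, N = N), class = "electrode_array")
}

# 8x8 trilinear hexahedral stiffness matrix for unit conductivity and
# element edge lengths hx, hy, hz (m), by 2x2x2 Gauss quadrature
hex_stiffness <- function(hx, hy, hz) {
  gp <- c(-1, 1) / sqrt(3)
  corners <- as.matrix(expand.grid(xi = c(-1, 1), eta = c(-1, 1), zeta = c(-1, 1)))
  K <- matrix(0, 8, 8)
  for (gx in gp) for (gy in gp) for (gz in gp) {
    # dN/dxi etc. at the Gauss point for the 8 corner shape functions
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      cx <- corners[a, 1]; cy <- corners[a, 2]; cz <- corners[a, 3]
      dN[a, 1] <- cx * (1 + cy * gy) * (1 + cz * gz) / 8
      dN[a, 2] <- (1 + cx * gx) * cy * (1 + cz * gz) / 8
      dN[a, 3] <- (1 + cx * gx) * (1 + cy * gy) * cz / 8
    }
    grad <- sweep(dN, 2L, c(2 / hx, 2 / hy, 2 / hz), `*`)
    K <- K + grad %*% t(grad) * (hx * hy * hz / 8)
  }
  K
}

#' Solve the volume-conductor lead field
#'
#' For each source, assembles the weak form of the heterogeneous Laplace
#' problem `div(sigma grad V) = 0` on the voxel mesh (trilinear hexahedral
#' elements, per-element conductivity from the voxel label), applies the
#' no-flux condition naturally on the skin-air interface, grounds the z-min
#' and z-max truncation planes (V = 0), injects unit current at the node
#' nearest the source position (reciprocity), and solves the sparse
#' symmetric system by Cholesky factorization. The resulting nodal field
#' h(l) is the voltage at l per unit source charge at the electrode, or
#' equivalently (by reciprocity) the electrode voltage per unit source at l.
#'
#' @param grid a [volume_grid()].
#' @param sources an [place_electrodes()] array, or an n x 3 matrix of
#'   source positions (mm) for validation studies with interior sources.
#' @param tol maximum admissible relative residual of the solve.
#' @return object of class `lead_field`: `h` is an `nx x ny x nz x n_src`
#'   array (V per unit current, zero on grounded planes and outside the
#'   conductive domain), plus `positions`, `electrodes` (if given), and the
#'   grid axes.
#' @export
solve_lead_field <- function(grid, sources, tol = 1e-8) {
  electrodes <- NULL
  if (inherits(sources, "electrode_array")) {
    electrodes <- sources
    src_pos <- sources$positions
  } else src_pos <- as.matrix(sources)
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  hx <- (grid$x[2] - grid$x[1]) / 1000  # mm -> m
  hy <- (grid$y[2] - grid$y[1]) / 1000
  hz <- (grid$z[2] - grid$z[1]) / 1000

  # element label = majority vote of its 8 corner labels (ties go to the
  # lower code, i.e. toward air), which keeps the discrete domain mirror
  # symmetric; air elements are excluded from the solve
  counts <- array(0L, dim = c(nx - 1L, ny - 1L, nz - 1L, 5L))
  for (lb in 0:4) {
    cnt <- array(0L, dim = c(nx - 1L, ny - 1L, nz - 1L))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      cnt <- cnt + (grid$labels[(1:(nx - 1L)) + di, (1:(ny - 1L)) + dj,
                                (1:(nz - 1L)) + dk, drop = FALSE] == lb)
    }
    counts[, , , lb + 1L] <- cnt
  }
  el_label <- array(max.col(matrix(counts, ncol = 5L),
                            ties.method = "first") - 1L,
                    dim = c(nx - 1L, ny - 1L, nz - 1L))
  el <- which(el_label != 0L, arr.ind = TRUE)
  if (nrow(el) == 0L) stop("no conductive elements in the grid")
  sig <- grid$sigma[el_label[el] + 1L]
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * as.integer(nx * ny)
  off <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  conn <- sapply(1:8, function(a)
    nid(el[, 1] + off[a, 1], el[, 2] + off[a, 2], el[, 3] + off[a, 3]))
  Kl <- hex_stiffness(hx, hy, hz)
  ii <- rep(conn, times = 8)
  jj <- conn[, rep(1:8, each = 8)]
  vv <- rep(sig, 64) * rep(as.vector(Kl), each = nrow(el))
  dim(jj) <- NULL

  n_nodes <- nx * ny * nz
  in_domain <- rep(FALSE, n_nodes)
  in_domain[unique(as.vector(conn))] <- TRUE
  kk <- ((seq_len(n_nodes) - 1L) %/% (nx * ny)) + 1L
  dirich <- in_domain & (kk == 1L | kk == nz)
  free <- which(in_domain & !dirich)
  remap <- integer(n_nodes); remap[free] <- seq_along(free)

  keep <- remap[ii] > 0L & remap[jj] > 0L
  K <- Matrix::sparseMatrix(i = remap[ii[keep]], j = remap[jj[keep]],
                            x = vv[keep], dims = c(length(free), length(free)))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  # direct Cholesky for small systems; Jacobi-preconditioned conjugate
  # gradients for large ones (the system is symmetric positive definite
  # once the truncation planes are grounded)
  use_direct <- length(free) <= 20000L
  if (use_direct) ch <- Matrix::Cholesky(K, LDL = FALSE, perm = TRUE)
  dinv <- 1 / Matrix::diag(K)

  solve_one <- function(b) {
    if (use_direct) return(as.numeric(Matrix::solve(ch, b)))
    x <- numeric(length(b))
    r <- b
    z <- dinv * r
    p <- z
    rz <- sum(r * z)
    bn <- sqrt(sum(b^2))
    for (it in seq_len(20000L)) {
      Kp <- as.numeric(K %*% p)
      alpha <- rz / sum(p * Kp)
      x <- x + alpha * p
      r <- r - alpha * Kp
      if (sqrt(sum(r^2)) <= tol * bn) return(x)
      z <- dinv * r
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    stop("lead-field CG solve did not converge within 20000 iterations")
  }

  n_src <- nrow(src_pos)
  h <- array(0, dim = c(nx, ny, nz, n_src))
  for (s in seq_len(n_src)) {
    idx3 <- grid_nearest_node(grid, src_pos[s, , drop = FALSE])
    node <- nid(idx3[1], idx3[2], idx3[3])
    if (!in_domain[node]) {
      # snap to the nearest in-domain node
      cand <- which(in_domain)
      ci <- ((cand - 1L) %% nx) + 1L
      cj <- (((cand - 1L) %/% nx) %% ny) + 1L
      ck <- ((cand - 1L) %/% (nx * ny)) + 1L
      d2 <- (grid$x[ci] - src_pos[s, 1])^2 + (grid$y[cj] - src_pos[s, 2])^2 +
        (grid$z[ck] - src_pos[s, 3])^2
      node <- cand[which.min(d2)]
    }
    if (remap[node] == 0L)
      stop("source node lies on a grounded truncation plane")
    b <- numeric(length(free)); b[remap[node]] <- 1
    v <- solve_one(b)
    res <- sqrt(sum((as.numeric(K %*% v) - b)^2)) / sqrt(sum(b^2))
    if (!is.finite(res) || res > tol)
      stop(sprintf("lead-field solve did not converge (relative residual %.2e)", res))
    hv <- numeric(n_nodes); hv[free] <- v
    h[, , , s] <- hv
  }
  structure(list(h = h, positions = src_pos, electrodes = electrodes,
                 x = grid$x, y = grid$y, z = grid$z), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d source(s) on a %d x %d x %d grid\n",
              dim(x$h)[4], length(x$x), length(x$y), length(x$z)))
  invisible(x)
}

#' Interpolate the lead field at arbitrary points
#'
#' Trilinear interpolation of each per-electrode nodal field at the given
#' 3D points. Points outside the grid bounding box are clamped to it
#' (`outside = "clamp"`) or rejected.
#'
#' @param lead a [solve_lead_field()] result.
#' @param pts n x 3 matrix (mm).
#' @param outside `"clamp"` or `"error"`.
#' @return n x n_electrodes matrix of h values.
#' @export
leadfield_interp <- function(lead, pts, outside = c("clamp", "error")) {
  outside <- match.arg(outside)
  pts <- matrix(as.numeric(pts), ncol = 3)
  cell <- function(ax, v) {
    if (outside == "error" && (any(v < ax[1] - 1e-9) || any(v > ax[length(ax)] + 1e-9)))
      stop("point outside the solve domain")
    v <- pmin(pmax(v, ax[1]), ax[length(ax)])
    i <- pmin(pmax(findInterval(v, ax), 1L), length(ax) - 1L)
    list(i = i, w = (v - ax[i]) / (ax[i + 1L] - ax[i]))
  }
  cx <- cell(lead$x, pts[, 1]); cy <- cell(lead$y, pts[, 2]); cz <- cell(lead$z, pts[, 3])
  nx <- length(lead$x); ny <- length(lead$y)
  n_src <- dim(lead$h)[4]
  out <- matrix(0, nrow(pts), n_src)
  for (s in seq_len(n_src)) {
    hs <- lead$h[, , , s]
    acc <- numeric(nrow(pts))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) cx$w else 1 - cx$w) * (if (dy) cy$w else 1 - cy$w) *
        (if (dz) cz$w else 1 - cz$w)
      lin <- (cx$i + dx) + (cy$i + dy - 1L) * nx + (cz$i + dz - 1L) * nx * ny
      acc <- acc + w * hs[lin]
    }
    out[, s] <- acc
  }
  out
}

#' Superpose traveling-pole potentials at the electrodes
#'
#' Per sample, the voltage at each electrode is the sum over active poles of
#' charge times the lead field interpolated at the pole position (linearity
#' of the volume conductor).
#'
#' @param lead a [solve_lead_field()] result.
#' @param poles either a single `pole_train` or a matrix with columns
#'   `sample` (1-based output sample), `x`, `y`, `z`, `amp`.
#' @param n_samples output length.
#' @param outside passed to [leadfield_interp()].
#' @return n_electrodes x n_samples matrix of voltages.
#' @export
superpose_potentials <- function(lead, poles, n_samples, outside = "clamp") {
  n_src <- dim(lead$h)[4]
  out <- matrix(0, n_src, n_samples)
  if (inherits(poles, "pole_train")) {
    p <- poles$poles
    samp <- as.integer(round(poles$t0 * poles$fs)) + 1L + as.integer(p[, "step"])
    poles <- cbind(sample = samp, p[, c("x", "y", "z", "amp"), drop = FALSE])
  }
  if (is.null(poles) || nrow(poles) == 0L) return(out)
  keep <- poles[, "sample"] >= 1L & poles[, "sample"] <= n_samples
  poles <- poles[keep, , drop = FALSE]
  if (nrow(poles) == 0L) return(out)
  hv <- leadfield_interp(lead, poles[, c("x", "y", "z"), drop = FALSE], outside)
  contrib <- hv * poles[, "amp"]
  agg <- rowsum(contrib, group = poles[, "sample"], reorder = FALSE)
  idx <- as.integer(rownames(agg))
  out[, idx] <- t(agg)
  out
}
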