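#' Cross-section stack
#'
#' Ordered stack of 2D fiber cross-section point sets, one per longitudinal
#' slice. Every layer must hold exactly the same number of points (one per
#' muscle fiber) and slice z positions must be strictly increasing.
#'
#' @param layers list of n_fib x 2 matrices (x, y in mm).
#' @param z_positions axial coordinate of each layer (mm), strictly
#'   increasing.
#' @return object of class `cross_section_stack`.
#' @export
cross_section_stack <- function(layers, z_positions) {
  counts <- vapply(layers, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop("invalid stack: layers have unequal point counts")
  if (length(z_positions) != length(layers) ||
      (length(z_positions) > 1L && any(diff(z_positions) <= 0)))
    stop("invalid stack: z_positions must be strictly increasing, one per layer")
  structure(list(layers = lapply(layers, function(l) {
    l <- as.matrix(l); colnames(l) <- c("x", "y"); l
  }), z_positions = z_positions, n_fib = counts[1]),
  class = "cross_section_stack")
}

#' @export
print.cross_section_stack <- function(x, ...) {
  cat(sprintf("<cross_section_stack> %d fibers x %d layers, z in [%g, %g] mm\n",
              x$n_fib, length(x$layers), min(x$z_positions), max(x$z_positions)))
  invisible(x)
}

#' Read a cross-section stack from CSV
#'
#' Expects columns `x`, `y`, `z`, `layer`; all points of a layer share its z.
#' @param path CSV path.
#' @return a [cross_section_stack()].
#' @export
read_stack_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z", "layer") %in% names(d)))
  ids <- sort(unique(d$layer))
  layers <- lapply(ids, function(i) as.matrix(d[d$layer == i, c("x", "y")]))
  z <- vapply(ids, function(i) d$z[d$layer == i][1], numeric(1))
  cross_section_stack(layers, z)
}

# Recursive bisection pairing between two equal-count point sets. Each
# subset is cut along its larger bounding-box extent (ties cut vertically,
# i.e. by x) into a lower ceiling(n/2) half and an upper floor(n/2) half;
# recursion bottoms out at singletons, which are paired.
pair_bisect <- function(A, B, ai = seq_len(nrow(A)), bi = seq_len(nrow(B))) {
  n <- length(ai)
  if (n != length(bi)) stop("pair_bisect: unequal point counts")
  if (n == 1L) return(cbind(a = ai, b = bi))
  split_half <- function(pts, idx) {
    ext <- c(diff(range(pts[idx, 1])), diff(range(pts[idx, 2])))
    dim <- if (ext[2] > ext[1]) 2L else 1L   # tie -> vertical cut (by x)
    ord <- idx[order(pts[idx, dim], pts[idx, 3L - dim])]
    k <- ceiling(n / 2)
    list(lo = ord[seq_len(k)], hi = ord[(k + 1L):n])
  }
  sa <- split_half(A, ai); sb <- split_half(B, bi)
  rbind(pair_bisect(A, B, sa$lo, sb$lo), pair_bisect(A, B, sa$hi, sb$hi))
}

#' Build per-fiber 3D paths from a cross-section stack
#'
#' Connects the points of consecutive layers by recursive bisection pairing:
#' each paired layer's point set is divided, along its larger bounding-box
#' extent, into two halves with equal point counts; the division recurses
#' until singleton cells, which are paired. Composing the per-pair bijections
#' across all layers yields one polyline (one waypoint per layer) per fiber.
#'
#' @param stack a [cross_section_stack()].
#' @param seed unused (the pairing is deterministic); kept for interface
#'   symmetry with the other anatomy builders.
#' @return list of n_fib polylines, each an n_layers x 3 matrix (mm), ordered
#'   by the fiber's point index in the first layer.
#' @export
build_fiber_paths <- function(stack, seed = NULL) {
  stopifnot(inherits(stack, "cross_section_stack"))
  k <- length(stack$layers)
  n <- stack$n_fib
  # perms[[j]][i] = index in layer j+1 paired with point i of layer j
  perms <- vector("list", max(k - 1L, 0L))
  if (k > 1L) for (j in seq_len(k - 1L)) {
    pr <- pair_bisect(stack$layers[[j]], stack$layers[[j + 1L]])
    perm <- integer(n)
    perm[pr[, "a"]] <- pr[, "b"]
    perms[[j]] <- perm
  }
  lapply(seq_len(n), function(f) {
    idx <- f
    path <- matrix(NA_real_, k, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (j in seq_len(k)) {
      path[j, 1:2] <- stack$layers[[j]][idx, ]
      path[j, 3] <- stack$z_positions[j]
      if (j < k) idx <- perms[[j]][idx]
    }
    path
  })
}

#' Disperse a motor unit's fibers in the cross-section plane
#'
#' Draws `n` 2D offsets as `R * Gaus2D(0, lambda)`: an isotropic Gaussian
#' with per-axis standard deviation `lambda`, scaled by the dispersion radius
#' `R`. `R` carries the length unit (mm when dispersing into a real section);
#' `lambda` is dimensionless.
#'
#' @param R dispersion radius (> 0).
#' @param lambda dispersion standard deviation as a fraction of `R` (> 0).
#' @param n number of fibers.
#' @param seed optional RNG seed.
#' @return n x 2 matrix of offsets.
#' @export
disperse_motor_unit <- function(R, lambda, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (R <= 0 || lambda <= 0) stop("disperse_motor_unit: R and lambda must be positive")
  stopifnot(n >= 1)
  R * matrix(stats::rnorm(2 * n, 0, lambda), ncol = 2,
             dimnames = list(NULL, c("x", "y")))
}

# area (mm^2) of the convex hull of a 2D point set (shoelace)
section_area <- function(pts) {
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Draw a motor-unit layout
#'
#' Samples the number of motor units and their sizes from the configured
#' Gaussians, then adjusts the total by adding/removing one fiber at a time
#' from uniformly random units (never letting a unit drop below one fiber)
#' until the sizes sum exactly to `n_fib`. Each unit also receives dispersion
#' parameters R (% of muscle cross-section area) and lambda (fraction of R)
#' drawn from Gaussians whose means scale linearly with unit size across the
#' configured ranges, so small units disperse tightly and large units widely.
#'
#' @param cfg a [default_config()].
#' @param n_fib total fiber count the sizes must sum to.
#' @param seed optional RNG seed.
#' @return object of class `mu_layout`: `mu_sizes`, `R_pct`, `lambda_frac`.
#' @export
make_mu_layout <- function(cfg, n_fib = cfg$table1$n_fib, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t1 <- cfg$table1
  n_mu <- max(1L, as.integer(round(stats::rnorm(1, t1$mu_number[["avg"]],
                                                t1$mu_number[["std"]]))))
  sizes <- pmax(1L, as.integer(round(stats::rnorm(n_mu, t1$mu_size[["avg"]],
                                                  t1$mu_size[["std"]]))))
  delta <- n_fib - sum(sizes)
  while (delta != 0L) {
    i <- sample.int(n_mu, 1L)
    if (delta > 0L) { sizes[i] <- sizes[i] + 1L; delta <- delta - 1L }
    else if (sizes[i] > 1L) { sizes[i] <- sizes[i] - 1L; delta <- delta + 1L }
  }
  rel <- if (diff(range(sizes)) > 0)
    (sizes - min(sizes)) / diff(range(sizes)) else rep(0.5, n_mu)
  lin <- function(range) range[1] + rel * diff(range)
  draw <- function(means, range) {
    sd <- diff(range) / 20
    pmin(pmax(stats::rnorm(n_mu, means, sd), range[1]), range[2])
  }
  structure(list(mu_sizes = sizes,
                 R_pct = draw(lin(t1$R_range), t1$R_range),
                 lambda_frac = draw(lin(t1$lambda_range), t1$lambda_range) / 100),
            class = "mu_layout")
}

#' Assign motor units to fiber cross-section positions
#'
#' Iterates the motor units in random order. Each unit's dispersion cloud
#' (see [disperse_motor_unit()]) is re-centered on a randomly chosen
#' still-unassigned section point, and each dispersed fiber is then greedily
#' assigned to the nearest still-unassigned point. By construction this
#' terminates with a perfect matching: every section point ends up owned by
#' exactly one unit. The dispersion radius R, given as a percentage of the
#' section area, is converted to the radius of a disc covering that fraction
#' of the area.
#'
#' @param layout a [make_mu_layout()].
#' @param section_points n x 2 matrix of fiber positions (mm) in one
#'   cross-section; n must equal `sum(layout$mu_sizes)`.
#' @param seed optional RNG seed.
#' @return list (one element per motor unit, in original unit order) of
#'   section-point indices owned by that unit.
#' @export
assign_mus_to_positions <- function(layout, section_points, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(section_points)
  if (n != sum(layout$mu_sizes))
    stop("assign_mus_to_positions: point count != total dispersed fibers")
  area <- section_area(section_points)
  unassigned <- rep(TRUE, n)
  owner <- integer(n)
  n_mu <- length(layout$mu_sizes)
  for (mu in sample.int(n_mu)) {
    R_mm <- sqrt(layout$R_pct[mu] / 100 * area / pi)
    center_idx <- {
      cand <- which(unassigned)
      cand[sample.int(length(cand), 1L)]
    }
    center <- section_points[center_idx, ]
    disp <- disperse_motor_unit(R_mm, layout$lambda_frac[mu], layout$mu_sizes[mu])
    disp <- sweep(disp, 2L, center, `+`)
    for (f in seq_len(nrow(disp))) {
      cand <- which(unassigned)
      d2 <- (section_points[cand, 1] - disp[f, 1])^2 +
        (section_points[cand, 2] - disp[f, 2])^2
      pick <- cand[which.min(d2)]
      unassigned[pick] <- FALSE
      owner[pick] <- mu
    }
  }
  lapply(seq_len(n_mu), function(mu) which(owner == mu))
}

#' Assign fiber types toward target percentages
#'
#' Starts from a uniform-random type assignment and iteratively converts one
#' fiber at a time until the realized type percentages match the targets
#' within tolerance. Conversion candidates are drawn through three Gaussians
#' with equal standard deviation and means evenly spaced across the range of
#' motor-unit sizes: the lowest-mean Gaussian selects fibers (by their unit's
#' size) for conversion to type I, the middle to IIa, the highest to IIx.
#' Any unit may therefore contain any type, but slow fibers concentrate in
#' small units and fast fibers in large units.
#'
#' @param mu_size_per_fiber numeric vector: size of the owning motor unit,
#'   one entry per fiber.
#' @param targets named percentages `c(I=, IIa=, IIx=)`, non-negative,
#'   summing to 100.
#' @param seed optional RNG seed.
#' @param tol convergence tolerance in percentage points.
#' @param max_iter conversion cap; exceeded -> error reporting the achieved
#'   percentages.
#' @return factor of levels `I`, `IIa`, `IIx`, one per fiber.
#' @export
assign_fiber_types <- function(mu_size_per_fiber, targets, seed = NULL,
                               tol = 1, max_iter = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  lv <- c("I", "IIa", "IIx")
  targets <- targets[lv]
  if (any(targets < 0) || abs(sum(targets) - 100) > 1e-9)
    stop("targets must be non-negative and sum to 100")
  n <- length(mu_size_per_fiber)
  types <- sample.int(3L, n, replace = TRUE)
  rng <- range(mu_size_per_fiber)
  means <- seq(rng[1], rng[2], length.out = 3)
  sd <- max(diff(rng) / 6, .Machine$double.eps)
  for (iter in seq_len(max_iter)) {
    realized <- tabulate(types, 3L) / n * 100
    dev <- targets - realized
    # converged when within tolerance; zero-target types must be emptied
    if (max(abs(dev)) <= tol && all(realized[targets == 0] == 0)) {
      return(factor(lv[types], levels = lv))
    }
    to <- which.max(dev)                       # most under-represented
    over <- which(dev < 0)                     # donor types
    s <- stats::rnorm(1, means[to], sd)
    cand <- which(types %in% over)
    pick <- cand[which.min(abs(mu_size_per_fiber[cand] - s))]
    types[pick] <- to
  }
  realized <- tabulate(types, 3L) / n * 100
  stop(sprintf("fiber-type assignment did not converge; achieved %s",
               paste(sprintf("%s=%.2f%%", lv, realized), collapse = ", ")))
}

# affine map of v onto [lo, hi]; a (numerically) constant population maps
# to the midpoint
affine_to_range <- function(v, lo, hi) {
  rng <- range(v)
  if (diff(rng) <= 1e-9 * max(abs(rng))) return(rep((lo + hi) / 2, length(v)))
  lo + (v - rng[1]) / diff(rng) * (hi - lo)
}

#' Sample per-fiber physiological parameters
#'
#' Draws radius, intracellular conductivity, ACh threshold, twitch reference
#' force and rise/decay constants from the per-type Gaussians (truncated
#' positive), computes conduction velocity by affinely mapping the
#' population's `r * sigma_ic` products onto the configured range (a
#' constant population maps to the midpoint), and places each neuromuscular
#' junction at the intersection of the fiber polyline with the z-plane at a
#' Gaussian-drawn length fraction from the upper tendon (higher z).
#'
#' @param ftype factor (`I`/`IIa`/`IIx`) per fiber.
#' @param paths list of fiber polylines from [build_fiber_paths()].
#' @param mu_id owning motor unit per fiber.
#' @param cfg a [default_config()].
#' @param seed optional RNG seed.
#' @return object of class `anatomy`: `fibers` (data.frame, one row per
#'   fiber), `paths`, plus the seed used.
#' @export
sample_fiber_parameters <- function(ftype, paths, mu_id, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(ftype)
  if (n == 0L) stop("sample_fiber_parameters: empty fiber population")
  stopifnot(length(paths) == n, length(mu_id) == n)
  t1 <- cfg$table1
  draw <- function(field) {
    out <- numeric(n)
    for (tp in levels(ftype)) {
      i <- which(ftype == tp)
      g <- t1$fiber[[tp]][[field]]
      out[i] <- rnorm_pos(length(i), g[1], g[2])
    }
    out
  }
  r <- draw("r"); sigma_ic <- draw("sigma_ic"); thr <- draw("thr")
  F_base <- draw("F_base"); tau_up <- draw("tau_up"); tau_down <- draw("tau_down")
  cv <- affine_to_range(r * sigma_ic, t1$cv_range[1], t1$cv_range[2])
  nmj_frac <- pmin(pmax(stats::rnorm(n, t1$nmj_pos[["avg"]] / 100,
                                     t1$nmj_pos[["std"]] / 100), 0.05), 0.95)
  nmj <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  nmj_arc <- numeric(n)
  for (f in seq_len(n)) {
    p <- paths[[f]]
    zr <- range(p[, 3])
    z_t <- zr[2] - nmj_frac[f] * diff(zr)   # measured from the upper tendon
    cs <- polyline_arclength(p)
    if (nrow(p) == 1L) {
      nmj[f, ] <- p[1L, ]
      nmj_arc[f] <- 0
    } else {
      j <- min(max(findInterval(z_t, p[, 3], rightmost.closed = TRUE), 1L),
               nrow(p) - 1L)
      w <- if (p[j + 1L, 3] > p[j, 3]) (z_t - p[j, 3]) / (p[j + 1L, 3] - p[j, 3]) else 0
      w <- min(max(w, 0), 1)
      nmj[f, ] <- p[j, ] * (1 - w) + p[j + 1L, ] * w
      nmj_arc[f] <- cs[j] + w * (cs[j + 1L] - cs[j])
    }
  }
  fibers <- data.frame(
    id = seq_len(n), ftype = ftype, r = r, d = 2 * r, sigma_ic = sigma_ic,
    thr = thr, F_base = F_base, tau_up = tau_up, tau_down = tau_down,
    cv = cv, mu_id = mu_id,
    nmj_x = nmj[, 1], nmj_y = nmj[, 2], nmj_z = nmj[, 3],
    nmj_arc = nmj_arc, nmj_frac = nmj_frac)
  structure(list(fibers = fibers, paths = paths, seed = seed),
            class = "anatomy")
}

#' Build a complete muscle anatomy
#'
#' Convenience pipeline: fiber paths from the stack, motor-unit layout,
#' spatial unit-to-fiber assignment (on the middle layer's cross-section),
#' fiber-type assignment, and per-fiber parameter sampling.
#'
#' @param stack a [cross_section_stack()].
#' @param cfg a [default_config()].
#' @param seed RNG seed recorded in the output.
#' @return an `anatomy` object (see [sample_fiber_parameters()]).
#' @export
build_anatomy <- function(stack, cfg = default_config(), seed = 1L) {
  set.seed(seed)
  paths <- build_fiber_paths(stack)
  n <- stack$n_fib
  layout <- make_mu_layout(cfg, n_fib = n)
  mid <- (length(stack$layers) + 1L) %/% 2L
  membership <- assign_mus_to_positions(layout, stack$layers[[mid]])
  mu_id <- integer(n)
  for (mu in seq_along(membership)) mu_id[membership[[mu]]] <- mu
  mu_size_per_fiber <- layout$mu_sizes[mu_id]
  ftype <- assign_fiber_types(mu_size_per_fiber, cfg$fiber_type_pct)
  a <- sample_fiber_parameters(ftype, paths, mu_id, cfg, seed = NULL)
  a$layout <- layout
  a$seed <- seed
  a
}

#' @export
print.anatomy <- function(x, ...) {
  f <- x$fibers
  cat(sprintf("<anatomy> %d fibers, %d motor units; types: %s\n",
              nrow(f), length(unique(f$mu_id)),
              paste(sprintf("%s %.1f%%", levels(f$ftype),
                            100 * as.numeric(table(f$ftype)) / nrow(f)),
                    collapse = ", ")))
  cat(sprintf("  cv %.2f-%.2f m/s, r %.1f-%.1f um\n",
              min(f$cv), max(f$cv), min(f$r), max(f$r)))
  invisible(x)
}

#' Persist / load an anatomy bundle
#'
#' Writes the fiber table, the path waypoints and metadata as plain text
#' (CSV + JSON) under a directory; `read_anatomy` reconstructs the bundle.
#'
#' @param a an `anatomy`.
#' @param dir output directory (created if missing).
#' @return `read_anatomy` returns an `anatomy`.
#' @export
write_anatomy <- function(a, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(a$fibers, file.path(dir, "fibers.csv"), row.names = FALSE)
  paths <- do.call(rbind, lapply(seq_along(a$paths), function(f)
    cbind(fiber_id = f, layer = seq_len(nrow(a$paths[[f]])), a$paths[[f]])))
  utils::write.csv(as.data.frame(paths), file.path(dir, "paths.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = a$seed), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_anatomy
#' @export
read_anatomy <- function(dir) {
  fibers <- utils::read.csv(file.path(dir, "fibers.csv"))
  fibers$ftype <- factor(fibers$ftype, levels = c("I", "IIa", "IIx"))
  pd <- utils::read.csv(file.path(dir, "paths.csv"))
  paths <- lapply(split(pd, pd$fiber_id), function(d)
    as.matrix(d[order(d$layer), c("x", "y", "z")]))
  paths <- paths[order(as.integer(names(paths)))]
  names(paths) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(list(fibers = fibers, paths = paths, seed = meta$seed),
            class = "anatomy")
}
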