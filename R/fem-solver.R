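#' Structured triangular mesh of a device cross-section
#'
#' Builds a tensor-product triangulation of the layered rectangle with mesh
#' lines snapped to every electrode edge and band boundary. Node rows on
#' barrier/film interfaces are duplicated so the potential may jump; the jump
#' is coupled through the interface admittance during assembly.
#'
#' @param model a [device_model()].
#' @param refine uniform refinement factor (2 halves the element size).
#' @param hx,hy target element sizes, m (defaults 50 um laterally, 150 um
#'   vertically; thin bands always get at least 2 element rows).
#' @return an object of class \code{fem_mesh}: \code{nodes} (n x 2 coordinate
#'   matrix), \code{tri} (m x 3 indices), \code{tri_band} (band id per
#'   triangle), \code{interfaces} (per interface: upper/lower node rows and
#'   segment lengths), \code{electrodes} (per terminal: node indices and
#'   segment lengths).
#' @export
build_mesh <- function(model, refine = 1, hx = 5e-5, hy = 1.5e-4) {
  stopifnot(inherits(model, "device_model"), refine >= 1)

  # x coordinates: snap to electrode edges, subdivide to target hx / refine
  xb <- sort(unique(c(0, model$width,
                      unlist(lapply(model$electrodes, function(e) e$x)))))
  xs <- xb[1]
  for (k in seq_len(length(xb) - 1L)) {
    len <- xb[k + 1L] - xb[k]
    n <- max(1L, ceiling(len / hx * refine))
    xs <- c(xs, xb[k] + len * seq_len(n) / n)
  }
  nxp <- length(xs)

  # per-band y rows
  iface_y <- vapply(model$interfaces, function(i) i$y, numeric(1))
  nb <- length(model$bands)
  band_rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    t_b <- model$bands[[b]]$thickness
    n <- max(2L, ceiling(t_b / hy * refine))
    band_rows[[b]] <- model$ybreaks[b] + t_b * (0:n) / n
  }

  # assemble node rows top to bottom, duplicating rows at interfaces
  row_y <- numeric(0)
  band_top <- integer(nb); band_bot <- integer(nb)
  iface_up <- integer(length(model$interfaces))
  iface_dn <- integer(length(model$interfaces))
  for (b in seq_len(nb)) {
    ys_b <- band_rows[[b]]
    if (b == 1L) {
      row_y <- ys_b
      band_top[b] <- 1L
    } else {
      hit <- which(abs(iface_y - model$ybreaks[b]) <= 1e-12 * model$height)
      if (length(hit) == 1L) {
        # duplicated row: previous band keeps its bottom row, this band gets
        # a new coincident top row
        iface_up[hit] <- length(row_y)
        row_y <- c(row_y, ys_b)
        band_top[b] <- band_bot[b - 1L] + 1L
        iface_dn[hit] <- band_top[b]
      } else {
        row_y <- c(row_y, ys_b[-1L])
        band_top[b] <- band_bot[b - 1L]
      }
    }
    band_bot[b] <- length(row_y)
  }
  nrows <- length(row_y)
  node_id <- function(r, i) (r - 1L) * nxp + i

  nodes <- cbind(x = rep(xs, times = nrows), y = rep(row_y, each = nxp))

  # triangles band by band (two per quad cell)
  tri <- vector("list", nb)
  for (b in seq_len(nb)) {
    rs <- band_top[b]:(band_bot[b] - 1L)
    r <- rep(rs, each = nxp - 1L)
    i <- rep(seq_len(nxp - 1L), times = length(rs))
    a <- node_id(r, i); bb <- node_id(r, i + 1L)
    c_ <- node_id(r + 1L, i + 1L); d <- node_id(r + 1L, i)
    tri[[b]] <- rbind(cbind(a, bb, d), cbind(bb, c_, d))
  }
  tri_band <- rep(seq_len(nb), times = vapply(tri, nrow, integer(1)))
  tri <- do.call(rbind, tri)

  # interface node pairs and segment lengths
  seg_len <- diff(xs)
  interfaces <- lapply(seq_along(model$interfaces), function(k) {
    list(label = model$interfaces[[k]]$label,
         layers = model$interfaces[[k]]$layers,
         up = node_id(iface_up[k], seq_len(nxp)),
         down = node_id(iface_dn[k], seq_len(nxp)),
         seg_len = seg_len)
  })

  # electrode node runs along the top/bottom boundary rows
  electrodes <- lapply(model$electrodes, function(e) {
    r <- if (e$boundary == "top") 1L else nrows
    tol <- 1e-9 * model$width
    cols <- which(xs >= e$x[1] - tol & xs <= e$x[2] + tol)
    if (length(cols) < 2L) stop("electrode span resolves to < 2 mesh nodes",
                                call. = FALSE)
    list(nodes = node_id(r, cols), seg_len = diff(xs[cols]),
         potential = e$potential, type = e$type, layer = e$layer)
  })

  structure(list(nodes = nodes, tri = tri, tri_band = tri_band,
                 interfaces = interfaces, electrodes = electrodes,
                 n_nodes = nrow(nodes), xs = xs, row_y = row_y),
            class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("FEM mesh: %d nodes, %d P1 triangles, %d interface(s)\n",
              x$n_nodes, nrow(x$tri), length(x$interfaces)))
  invisible(x)
}

# accumulate sparse complex triplets for the electro-quasistatic weak form
# at one frequency; returns A (triplets), rhs b, and Dirichlet bookkeeping
.assemble_system <- function(model, mesh, f, potentials = NULL) {
  n <- mesh$n_nodes
  xy <- mesh$nodes
  T_ <- mesh$tri

  x1 <- xy[T_[, 1], 1]; x2 <- xy[T_[, 2], 1]; x3 <- xy[T_[, 3], 1]
  y1 <- xy[T_[, 1], 2]; y2 <- xy[T_[, 2], 2]; y3 <- xy[T_[, 3], 2]
  area <- 0.5 * abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  bmat <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cmat <- cbind(x3 - x2, x1 - x3, x2 - x1)

  if (is.null(model$material_fn)) {
    sig_band <- vapply(model$bands,
                       function(b) complex_conductivity(b$material, f),
                       complex(1))
    sig <- sig_band[mesh$tri_band]
  } else {
    sig <- model$material_fn((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3, f)
  }
  coef <- model$depth * sig / (4 * area)

  m <- nrow(T_)
  ii <- integer(9L * m); jj <- integer(9L * m); vv <- complex(9L * m)
  k <- 0L
  for (p in 1:3) for (q in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- T_[, p]; jj[idx] <- T_[, q]
    vv[idx] <- coef * (bmat[, p] * bmat[, q] + cmat[, p] * cmat[, q])
    k <- k + 1L
  }

  b <- complex(n)

  # interior thin-layer jump conditions: n.J = Ys (V+ - V-)
  for (ifc in mesh$interfaces) {
    ys <- admittance_per_area(ifc$layers, f)
    for (s in seq_along(ifc$seg_len)) {
      L <- model$depth * ifc$seg_len[s] * ys
      u <- ifc$up[s:(s + 1L)]; d <- ifc$down[s:(s + 1L)]
      M11 <- L / 3; M12 <- L / 6
      add_i <- c(u[1], u[2], u[1], u[2],  d[1], d[2], d[1], d[2],
                 u[1], u[2], u[1], u[2])
      add_j <- c(u[1], u[2], u[2], u[1],  d[1], d[2], d[2], d[1],
                 d[1], d[2], d[2], d[1])
      add_v <- c(M11, M11, M12, M12,  M11, M11, M12, M12,
                 -M11, -M11, -M12, -M12)
      # the cross block is symmetric: also (down, up)
      add_i <- c(add_i, d[1], d[2], d[1], d[2])
      add_j <- c(add_j, u[1], u[2], u[2], u[1])
      add_v <- c(add_v, -M11, -M11, -M12, -M12)
      ii <- c(ii, add_i); jj <- c(jj, add_j); vv <- c(vv, add_v)
    }
  }

  # electrode terminals
  dir_nodes <- integer(0); dir_vals <- complex(0)
  for (nm in names(mesh$electrodes)) {
    e <- mesh$electrodes[[nm]]
    pot <- if (!is.null(potentials)) potentials[[nm]] else e$potential
    if (e$type == "dirichlet") {
      dir_nodes <- c(dir_nodes, e$nodes)
      dir_vals <- c(dir_vals, rep(as.complex(pot), length(e$nodes)))
    } else {
      ys <- admittance_per_area(e$layer, f)
      for (s in seq_along(e$seg_len)) {
        L <- model$depth * e$seg_len[s] * ys
        nd <- e$nodes[s:(s + 1L)]
        ii <- c(ii, nd[1], nd[2], nd[1], nd[2])
        jj <- c(jj, nd[1], nd[2], nd[2], nd[1])
        vv <- c(vv, L / 3, L / 3, L / 6, L / 6)
        b[nd] <- b[nd] + pot * L / 2
      }
    }
  }

  list(ii = ii, jj = jj, vv = vv, b = b, n = n,
       dir_nodes = dir_nodes, dir_vals = dir_vals)
}

#' Assemble the frequency-domain linear system
#'
#' Weak form of the electro-quasistatic balance
#' \eqn{\nabla\cdot(\sigma^*\nabla V) = 0} with P1 triangular elements,
#' interior thin-layer jump conditions \eqn{n\cdot J = Y_s(V^+ - V^-)} on
#' barrier/film interfaces, and either contact-impedance (robin) or strong
#' Dirichlet electrode terminals. The system is complex symmetric and sparse.
#'
#' @param model a [device_model()].
#' @param f frequency, Hz.
#' @param mesh a [build_mesh()] result (built on demand if NULL).
#' @param potentials optional named terminal-potential overrides, V.
#' @return a list with the complex system matrix \code{A}
#'   (\code{Matrix::sparseMatrix} pair \code{Ar}, \code{Ai}), right-hand side
#'   \code{b}, Dirichlet bookkeeping and the mesh.
#' @export
assemble <- function(model, f, mesh = NULL, potentials = NULL) {
  stopifnot(inherits(model, "device_model"), is.finite(f), f >= 0)
  if (is.null(mesh)) mesh <- build_mesh(model)
  sys <- .assemble_system(model, mesh, f, potentials)
  Ar <- Matrix::sparseMatrix(i = sys$ii, j = sys$jj, x = Re(sys$vv),
                             dims = c(sys$n, sys$n))
  Ai <- Matrix::sparseMatrix(i = sys$ii, j = sys$jj, x = Im(sys$vv),
                             dims = c(sys$n, sys$n))
  if (length(sys$dir_nodes) == 0L &&
      all(vapply(mesh$electrodes, function(e) e$type, character(1)) != "robin"))
    stop("assembly produced a singular system: no grounded terminal",
         call. = FALSE)
  list(Ar = Ar, Ai = Ai, b = sys$b, dir_nodes = sys$dir_nodes,
       dir_vals = sys$dir_vals, mesh = mesh, f = f, model = model)
}

# solve the complex sparse system via the equivalent 2n x 2n real block form
.solve_complex <- function(Ar, Ai, b) {
  n <- length(b)
  B <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  x <- Matrix::solve(B, c(Re(b), Im(b)))
  x <- as.numeric(x)
  complex(real = x[seq_len(n)], imaginary = x[n + seq_len(n)])
}

#' Solve one frequency of the forward model
#'
#' Solves the assembled system and extracts the terminal current by
#' variationally consistent integration (nodal reactions at Dirichlet
#' terminals; \eqn{I = d\,Y_s \int (V_{app} - V)\,ds} at contact-impedance
#' terminals), the terminal impedance \eqn{Z = \Delta V_{applied} / I_{drive}},
#' and a current-conservation residual.
#'
#' @param model a [device_model()].
#' @param f frequency, Hz.
#' @param mesh optional prebuilt [build_mesh()] (rebuilt if NULL).
#' @param potentials optional named terminal-potential overrides, V (e.g.
#'   \code{list(we = 0, ce = 0.01)} to swap driven and grounded terminals).
#' @return an object of class \code{fem_solution}: complex nodal potential
#'   \code{v}, per-terminal complex currents (A, positive into the domain),
#'   terminal impedance \code{z} (ohm), conservation residual, frequency, mesh.
#' @export
solve_frequency <- function(model, f, mesh = NULL, potentials = NULL) {
  if (is.null(mesh)) mesh <- build_mesh(model)
  sys <- .assemble_system(model, mesh, f, potentials)
  n <- sys$n

  pot <- vapply(names(mesh$electrodes), function(nm) {
    if (!is.null(potentials)) potentials[[nm]]
    else mesh$electrodes[[nm]]$potential
  }, numeric(1))

  Ar <- Matrix::sparseMatrix(i = sys$ii, j = sys$jj, x = Re(sys$vv),
                             dims = c(n, n))
  Ai <- Matrix::sparseMatrix(i = sys$ii, j = sys$jj, x = Im(sys$vv),
                             dims = c(n, n))

  if (length(sys$dir_nodes)) {
    dn <- sys$dir_nodes
    keep <- !duplicated(dn)
    dn <- dn[keep]; dv <- sys$dir_vals[keep]
    free <- setdiff(seq_len(n), dn)
    vd <- complex(n); vd[dn] <- dv
    Avd <- (as.numeric(Ar %*% Re(vd)) - as.numeric(Ai %*% Im(vd))) +
      1i * (as.numeric(Ar %*% Im(vd)) + as.numeric(Ai %*% Re(vd)))
    rhs <- sys$b - Avd
    v <- vd
    v[free] <- .solve_complex(Ar[free, free, drop = FALSE],
                              Ai[free, free, drop = FALSE],
                              rhs[free])
  } else {
    v <- .solve_complex(Ar, Ai, sys$b)
  }

  # full-matrix product for reactions and conservation checks
  Av <- as.numeric(Ar %*% Re(v) - Ai %*% Im(v)) +
    1i * as.numeric(Ar %*% Im(v) + Ai %*% Re(v))
  resid <- Av - sys$b

  currents <- vapply(names(mesh$electrodes), function(nm) {
    e <- mesh$electrodes[[nm]]
    if (e$type == "dirichlet") {
      sum(resid[e$nodes])
    } else {
      ys <- admittance_per_area(e$layer, f)
      vm <- v[e$nodes]
      seg_int <- (vm[-length(vm)] + vm[-1]) / 2 * e$seg_len
      model$depth * ys * (pot[[nm]] * sum(e$seg_len) - sum(seg_int))
    }
  }, complex(1))

  i_scale <- max(Mod(currents))
  conservation <- if (i_scale > 0) Mod(sum(currents)) / i_scale else 0

  drive <- names(pot)[which.max(abs(pot))]
  others <- setdiff(names(pot), drive)
  dv_applied <- pot[[drive]] - pot[[others[1]]]
  i_drive <- currents[[drive]]
  if (Mod(i_drive) == 0) stop(sprintf(
    "linear solve failed at f = %g Hz: zero terminal current", f), call. = FALSE)
  z <- dv_applied / i_drive

  structure(list(mesh = mesh, f = f, v = v, currents = currents, z = z,
                 conservation = conservation, potentials = pot,
                 model = model),
            class = "fem_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("FEM solution at %.4g Hz: Z = %.4g %+.4gi ohm (|Z| = %.4g), conservation %.2g\n",
              x$f, Re(x$z), Im(x$z), Mod(x$z), x$conservation))
  invisible(x)
}

#' Frequency sweep of the forward model
#'
#' Per-frequency solves over a grid, returning the terminal impedance as an
#' [impedance_spectrum()] in the shared dialect so [fit_spectrum()] can consume
#' simulated data directly.
#'
#' @param model a [device_model()].
#' @param grid a [frequency_grid()].
#' @param mesh optional prebuilt mesh (reused across frequencies).
#' @param ... metadata passed to [impedance_spectrum()].
#' @return an [impedance_spectrum()] (attribute \code{conservation} carries the
#'   worst per-frequency conservation residual).
#' @export
fem_sweep <- function(model, grid = default_grid(), mesh = NULL, ...) {
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  if (is.null(mesh)) mesh <- build_mesh(model)
  fs <- as.numeric(grid)
  z <- complex(length(fs))
  cons <- numeric(length(fs))
  for (k in seq_along(fs)) {
    sol <- tryCatch(solve_frequency(model, fs[k], mesh = mesh),
                    error = function(e) stop(sprintf(
                      "sweep failed at f = %g Hz: %s", fs[k],
                      conditionMessage(e)), call. = FALSE))
    z[k] <- sol$z
    cons[k] <- sol$conservation
  }
  sp <- impedance_spectrum(grid, z, well = model$scenario, ...)
  attr(sp, "conservation") <- max(cons)
  sp
}

#' Potential-magnitude map of a solution
#'
#' Tabulates |V| and phase on the mesh nodes (a regular raster by
#' construction), optionally appending the equipotential electrode terminals
#' (the metal side of the contact layer, at the applied potential) so the full
#' applied-potential range is present in the map. Per-band summaries are
#' attached as the \code{layers} attribute.
#'
#' @param solution a [solve_frequency()] result.
#' @param include_terminals append terminal rows (default TRUE).
#' @return data.frame \code{x_m}, \code{y_m}, \code{v_abs}, \code{v_phase_deg},
#'   \code{part} (\code{"domain"} or \code{"terminal"}).
#' @export
potential_map <- function(solution, include_terminals = TRUE) {
  stopifnot(inherits(solution, "fem_solution"))
  mesh <- solution$mesh
  out <- data.frame(x_m = mesh$nodes[, 1], y_m = mesh$nodes[, 2],
                    v_abs = Mod(solution$v),
                    v_phase_deg = Arg(solution$v) * 180 / pi,
                    part = "domain", stringsAsFactors = FALSE)
  if (include_terminals) {
    for (nm in names(mesh$electrodes)) {
      e <- mesh$electrodes[[nm]]
      pot <- solution$potentials[[nm]]
      out <- rbind(out, data.frame(
        x_m = mesh$nodes[e$nodes, 1], y_m = mesh$nodes[e$nodes, 2],
        v_abs = rep(abs(pot), length(e$nodes)),
        v_phase_deg = 0, part = "terminal", stringsAsFactors = FALSE))
    }
  }
  ybreaks <- solution$model$ybreaks
  band_of <- findInterval(mesh$nodes[, 2], ybreaks, rightmost.closed = TRUE)
  band_of <- pmin(pmax(band_of, 1L), length(solution$model$bands))
  summaries <- do.call(rbind, lapply(seq_along(solution$model$bands),
    function(b) {
      sel <- band_of == b
      data.frame(band = solution$model$bands[[b]]$name,
                 v_abs_mean = mean(Mod(solution$v[sel])),
                 v_abs_max = max(Mod(solution$v[sel])))
    }))
  attr(out, "layers") <- summaries
  out
}

#' Per-barrier fraction of the applied potential dropped at each interface
#'
#' For every barrier interface, the length-weighted mean of the potential jump
#' magnitude |V+ - V-| across the interface divided by the applied terminal
#' potential difference: the selectivity metric of the simulation study. A
#' device placed on one face of a multi-barrier stack confines the field to the
#' nearest cell layer, so the near-barrier fraction dominates the far one.
#'
#' @param solution a [solve_frequency()] result.
#' @param model the [device_model()] (defaults to the solution's model).
#' @return named numeric vector of fractions in [0, 1], one per interface.
#' @export
selectivity_metric <- function(solution, model = solution$model) {
  stopifnot(inherits(solution, "fem_solution"))
  if (length(solution$mesh$interfaces) == 0L)
    stop("selectivity_metric requires a model with >= 1 barrier interface",
         call. = FALSE)
  pot <- solution$potentials
  dv_applied <- abs(max(pot) - min(pot))
  out <- vapply(solution$mesh$interfaces, function(ifc) {
    jump <- Mod(solution$v[ifc$up] - solution$v[ifc$down])
    # trapezoid weights along the interface
    w <- c(ifc$seg_len / 2, 0) + c(0, ifc$seg_len / 2)
    sum(jump * w) / sum(w) / dv_applied
  }, numeric(1))
  names(out) <- vapply(solution$mesh$interfaces, function(i) i$label,
                       character(1))
  out
}
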