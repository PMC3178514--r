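#' Build the disc source space inside a three-sphere head model
#'
#' Constructs a single axial slice of dipoles/voxels on a regular square grid,
#' keeping cells whose centers fall inside the cross-section of the innermost
#' ("brain") sphere and outside two circular holes that stand in for white
#' matter. Four disjoint source patches are carved out of the surviving cells.
#'
#' All geometry is expressed in normalized head units in which the scalp
#' radius is 1 and 1 unit corresponds to 100 mm, so the default 18 mm slice
#' sits at z = 0.18 and the 200 mm field of view spans \[-1, 1\].
#'
#' The hole radii are calibrated deterministically: the number of grid cells
#' inside the brain cross-section generally exceeds the target dipole count,
#' and the excess is removed by growing the two holes cell-by-cell (nearest
#' cells to each hole center first, split evenly between the holes) until
#' exactly `n_dipoles` cells survive.
#'
#' @param grid_size cells per grid side (default 70).
#' @param fov_mm physical field of view in mm (default 200).
#' @param slice_z_mm slice height in mm above the sphere center (default 18).
#' @param sphere_radii radii of brain, skull and scalp spheres in normalized
#'   units, strictly increasing (default `c(0.87, 0.89, 1)`).
#' @param n_dipoles surviving cell count the hole calibration aims for
#'   (default 2452). Use `NA` to keep all in-circle cells (no holes).
#' @param hole_centers 2x2 matrix of hole centers (rows) in normalized units.
#' @param source_centers 4x2 matrix of patch centers (rows) in normalized
#'   units, one per source S1..S4.
#' @param source_sizes dipole count per source (default `c(90, 30, 32, 100)`).
#'
#' @return An object of class `source_disc` with fields `positions`
#'   (dipoles x 3), `grid_index` (dipoles x 2 row/col), `hole_mask` (logical
#'   over the full grid), `source_masks` (list of four dipole index sets),
#'   `slice_z`, `fov_mm`, `grid_size`, `sphere_radii`.
#' @export
build_source_disc <- function(grid_size = 70,
                              fov_mm = 200,
                              slice_z_mm = 18,
                              sphere_radii = c(0.87, 0.89, 1),
                              n_dipoles = 2452,
                              hole_centers = rbind(c(-0.25, -0.20),
                                                   c( 0.25, -0.20)),
                              source_centers = rbind(c( 0.00, -0.60),
                                                     c( 0.50,  0.30),
                                                     c(-0.50,  0.30),
                                                     c( 0.00,  0.55)),
                              source_sizes = c(90, 30, 32, 100)) {
  stopifnot(grid_size >= 2, length(sphere_radii) == 3)
  if (any(diff(sphere_radii) <= 0))
    stop("sphere_radii must be strictly increasing")
  scale_mm <- 100 * sphere_radii[3]      # 1 normalized unit per 100 mm scalp
  slice_z <- slice_z_mm / scale_mm
  fov <- fov_mm / scale_mm
  r_brain <- sphere_radii[1]
  if (abs(slice_z) >= r_brain)
    stop("slice lies outside the brain sphere (|z| >= innermost radius)")
  r_disc <- sqrt(r_brain^2 - slice_z^2)

  cell <- fov / grid_size
  centers <- (seq_len(grid_size) - 0.5) * cell - fov / 2
  grid <- expand.grid(col = seq_len(grid_size), row = seq_len(grid_size))
  gx <- centers[grid$col]
  gy <- centers[grid$row]
  in_circle <- gx^2 + gy^2 < r_disc^2

  hole_mask <- rep(FALSE, grid_size^2)
  if (!is.na(n_dipoles)) {
    excess <- sum(in_circle) - n_dipoles
    if (excess < 0)
      stop("requested n_dipoles exceeds the number of in-circle grid cells (",
           sum(in_circle), ")")
    if (excess > 0) {
      take <- c(ceiling(excess / 2), floor(excess / 2))
      idx_in <- which(in_circle)
      for (h in 1:2) {
        if (take[h] == 0) next
        d2 <- (gx[idx_in] - hole_centers[h, 1])^2 +
              (gy[idx_in] - hole_centers[h, 2])^2
        avail <- which(!hole_mask[idx_in])
        ord <- avail[order(d2[avail], avail)]
        hole_mask[idx_in[ord[seq_len(take[h])]]] <- TRUE
      }
    }
  }

  keep <- in_circle & !hole_mask
  pos <- cbind(x = gx[keep], y = gy[keep], z = slice_z)
  nd <- nrow(pos)

  # disjoint per-source patches: nearest surviving cells to each center,
  # assigned greedily in source order
  masks <- vector("list", 4)
  taken <- rep(FALSE, nd)
  for (s in 1:4) {
    d2 <- (pos[, 1] - source_centers[s, 1])^2 +
          (pos[, 2] - source_centers[s, 2])^2
    avail <- which(!taken)
    if (length(avail) < source_sizes[s])
      stop("source template incompatible with hole placement: not enough ",
           "free dipoles for source ", s)
    ord <- avail[order(d2[avail], avail)]
    masks[[s]] <- sort(ord[seq_len(source_sizes[s])])
    taken[masks[[s]]] <- TRUE
  }
  names(masks) <- paste0("S", 1:4)

  structure(
    list(positions = pos,
         grid_index = cbind(row = grid$row[keep], col = grid$col[keep]),
         hole_mask = hole_mask,
         source_masks = masks,
         slice_z = slice_z,
         fov_mm = fov_mm,
         grid_size = grid_size,
         sphere_radii = sphere_radii),
    class = "source_disc")
}

#' @export
print.source_disc <- function(x, ...) {
  cat("<source_disc> ", nrow(x$positions), " dipoles on a ",
      x$grid_size, "x", x$grid_size, " grid (FOV ", x$fov_mm,
      " mm, slice z = ", signif(x$slice_z, 3), ")\n", sep = "")
  cat("  source patch sizes:",
      paste(vapply(x$source_masks, length, 1L), collapse = ", "), "\n")
  invisible(x)
}

#' Electrode montage on the upper hemisphere
#'
#' Places `n` electrodes on the unit upper hemisphere. The default scheme is a
#' quasi-uniform Fibonacci spiral; alternatively electrode positions can be
#' read from a whitespace-delimited "label x y z" file via [read_montage()].
#'
#' @param n_electrodes number of electrodes (default 62).
#' @return An object of class `montage` with `positions` (n x 3, unit norm,
#'   z >= 0) and `labels`.
#' @export
build_montage <- function(n_electrodes = 62) {
  n <- as.integer(n_electrodes)
  if (is.na(n) || n < 1) stop("n_electrodes must be a positive integer")
  if (n == 1) {
    pos <- matrix(c(0, 0, 1), 1, 3)
  } else {
    k <- seq_len(n)
    z <- 1 - (k - 0.5) / n            # (0, 1): pole-most first, all z >= 0
    phi <- k * pi * (3 - sqrt(5))     # golden angle
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- cbind(r * cos(phi), r * sin(phi), z)
  }
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos,
                 labels = sprintf("E%02d", seq_len(n))),
            class = "montage")
}

#' Read an electrode-position file
#'
#' Expects one electrode per line: `label x y z` (whitespace-delimited).
#' Positions are projected onto the unit sphere; a warning is issued when a
#' point is off the sphere by more than `tol`.
#'
#' @param file path to the position file.
#' @param tol relative radius tolerance before a projection warning (1e-6).
#' @return A `montage` object.
#' @export
read_montage <- function(file, tol = 1e-6) {
  tab <- tryCatch(utils::read.table(file, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("malformed position file: ",
                                           conditionMessage(e)))
  if (ncol(tab) < 4) stop("malformed position file: need 'label x y z'")
  pos <- as.matrix(tab[, 2:4])
  if (!is.numeric(pos) || anyNA(pos)) stop("malformed position file: non-numeric coordinates")
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("malformed position file: zero-length position")
  if (any(abs(nrm - 1) > tol))
    warning(sum(abs(nrm - 1) > tol),
            " electrode(s) off the unit sphere; projected onto it")
  pos <- pos / nrm
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, labels = as.character(tab[[1]])),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", nrow(x$positions), " electrodes, z in [",
      signif(min(x$positions[, 3]), 3), ", ",
      signif(max(x$positions[, 3]), 3), "]\n", sep = "")
  invisible(x)
}

# Per-harmonic radial solution of the three-shell Poisson problem.
#
# For each spherical-harmonic degree n the potential in shell j is
# A_j r^n + B_j r^-(n+1); the dipole's primary potential contributes a known
# r^-(n+1) term in the innermost shell. Continuity of potential and of radial
# current at the two interfaces plus the insulating outer boundary give a
# 5x5 linear system per degree, whose solution yields the scalp-surface
# response g_n per unit primary coefficient. Independent of dipole depth,
# so it is solved once per degree.
.shell_response <- function(L, radii, cond) {
  a <- radii[1]; b <- radii[2]; R <- radii[3]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  g <- numeric(L)
  for (n in seq_len(L)) {
    M <- matrix(0, 5, 5)
    # unknowns: A1, A2, B2, A3, B3
    M[1, ] <- c(a^n, -a^n, -a^(-(n + 1)), 0, 0)
    M[2, ] <- c(s1 * n * a^(n - 1), -s2 * n * a^(n - 1),
                s2 * (n + 1) * a^(-(n + 2)), 0, 0)
    M[3, ] <- c(0, b^n, b^(-(n + 1)), -b^n, -b^(-(n + 1)))
    M[4, ] <- c(0, s2 * n * b^(n - 1), -s2 * (n + 1) * b^(-(n + 2)),
                -s3 * n * b^(n - 1), s3 * (n + 1) * b^(-(n + 2)))
    M[5, ] <- c(0, 0, 0, n * R^(n - 1), -(n + 1) * R^(-(n + 2)))
    rhs <- c(-a^(-(n + 1)), s1 * (n + 1) * a^(-(n + 2)), 0, 0, 0)
    # column equilibration: raw columns span ~a^n .. a^-(n+2), which is
    # numerically singular at high order although the system is benign
    cs <- apply(abs(M), 2, max)
    x <- solve(M / rep(cs, each = 5), rhs) / cs
    g[n] <- x[4] * R^n + x[5] * R^(-(n + 1))
  }
  g
}

# Legendre P_n(x) and associated P_n^1(x) = sqrt(1-x^2) P_n'(x) (no
# Condon-Shortley phase) for n = 1..L, x a vector; returns two L x length(x)
# matrices filled by upward recurrence.
.legendre_series <- function(L, x) {
  nx <- length(x)
  P <- matrix(0, L, nx)
  P1 <- matrix(0, L, nx)
  s <- sqrt(pmax(0, 1 - x^2))
  P[1, ] <- x
  P1[1, ] <- s
  if (L >= 2) {
    P[2, ] <- 1.5 * x^2 - 0.5
    P1[2, ] <- 3 * x * s
    pm2 <- P[1, ]; pm1 <- P[2, ]
    qm2 <- P1[1, ]; qm1 <- P1[2, ]
    for (n in 3:L) {
      pn <- ((2 * n - 1) * x * pm1 - (n - 1) * pm2) / n
      qn <- ((2 * n - 1) * x * qm1 - n * qm2) / (n - 1)
      P[n, ] <- pn; P1[n, ] <- qn
      pm2 <- pm1; pm1 <- pn
      qm2 <- qm1; qm1 <- qn
    }
  }
  list(P = P, P1 = P1)
}

#' Analytic lead field of the concentric three-sphere head model
#'
#' Computes the electrodes x dipoles gain matrix of the quasi-static EEG
#' forward problem for dipoles inside the innermost of three concentric
#' spheres, using the Legendre-series solution with per-degree radial
#' transfer coefficients. The truncation order is doubled adaptively until
#' the scalp potentials change by less than `tol` (relative), and the average
#' reference is applied (each column has zero mean over electrodes).
#'
#' @param montage a [build_montage()] object.
#' @param disc a [build_source_disc()] object (or any dipoles x 3 position
#'   matrix in normalized units).
#' @param sphere_radii brain/skull/scalp radii (default taken from `disc`).
#' @param conductivities shell conductivities, brain:skull:scalp; default
#'   `c(1, 1/80, 1)`, the classic three-sphere convention.
#' @param orientation common dipole moment as a 3-vector; default `c(0, 0, 1)`
#'   (unit moment normal to the disc plane).
#' @param truncation initial Legendre truncation order (default 60).
#' @param tol relative convergence tolerance for adaptive order doubling.
#' @param max_order hard cap on the truncation order (default 512).
#' @return An object of class `leadfield`: list with `gain` (electrodes x
#'   dipoles, average-referenced), `reference = "average"`, plus the geometry
#'   metadata used.
#' @export
compute_leadfield <- function(montage, disc,
                              sphere_radii = NULL,
                              conductivities = c(1, 1 / 80, 1),
                              orientation = c(0, 0, 1),
                              truncation = 60,
                              tol = 1e-8,
                              max_order = 512) {
  pos <- if (inherits(disc, "source_disc")) disc$positions else as.matrix(disc)
  if (is.null(sphere_radii))
    sphere_radii <- if (inherits(disc, "source_disc")) disc$sphere_radii
                    else c(0.87, 0.89, 1)
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  b_all <- sqrt(rowSums(pos^2))
  if (any(b_all >= sphere_radii[1]))
    stop("all dipoles must lie strictly inside the innermost sphere")
  elec <- montage$positions

  L <- as.integer(truncation)
  X <- .leadfield_series(elec, pos, sphere_radii, conductivities,
                         orientation, L)
  repeat {
    if (2L * L > max_order) {
      warning("lead-field series not converged at order ", L,
              " (tolerance ", tol, "); result returned at this order")
      break
    }
    X2 <- .leadfield_series(elec, pos, sphere_radii, conductivities,
                            orientation, 2L * L)
    rel <- max(abs(X2 - X)) / max(abs(X2))
    X <- X2
    L <- 2L * L
    if (rel < tol) break
  }

  X <- sweep(X, 2, colMeans(X))  # average reference
  dimnames(X) <- list(montage$labels, NULL)
  structure(list(gain = X,
                 reference = "average",
                 sphere_radii = sphere_radii,
                 conductivities = conductivities,
                 orientation = orientation,
                 order = L),
            class = "leadfield")
}

# raw (unreferenced) series evaluation at a fixed truncation order
.leadfield_series <- function(elec, pos, radii, cond, orientation, L) {
  ne <- nrow(elec)
  nd <- nrow(pos)
  g <- .shell_response(L, radii, cond)
  ns <- seq_len(L)
  X <- matrix(0, ne, nd)
  for (d in seq_len(nd)) {
    p <- pos[d, ]
    b <- sqrt(sum(p^2))
    if (b < 1e-12) {
      phat <- orientation / sqrt(sum(orientation^2))
      qr <- sqrt(sum(orientation^2)); qtv <- c(0, 0, 0)
    } else {
      phat <- p / b
      qr <- sum(orientation * phat)
      qtv <- orientation - qr * phat
    }
    qt <- sqrt(sum(qtv^2))
    cth <- as.numeric(elec %*% phat)
    cth <- pmin(1, pmax(-1, cth))
    if (qt > 1e-14) {
      that <- qtv / qt
      eperp <- elec - outer(cth, phat)
      en <- sqrt(rowSums(eperp^2))
      cphi <- ifelse(en > 1e-14, as.numeric(eperp %*% that) / en, 0)
    } else {
      cphi <- numeric(ne)
    }
    leg <- .legendre_series(L, cth)
    bpow <- if (b < 1e-12) c(1, numeric(L - 1)) else b^(ns - 1)
    crad <- qr * ns * bpow / (4 * pi * cond[1])
    ctan <- qt * bpow / (4 * pi * cond[1])
    # V(e) = sum_n g_n [ c_rad,n P_n(cos th) + c_tan,n P^1_n(cos th) cos phi ]
    X[, d] <- as.numeric(crossprod(leg$P, g * crad)) +
              cphi * as.numeric(crossprod(leg$P1, g * ctan))
  }
  X
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$gain), " electrodes x ", ncol(x$gain),
      " dipoles (order ", x$order, ", ", x$reference, " reference)\n",
      sep = "")
  invisible(x)
}
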