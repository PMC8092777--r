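#' Fish body-model dimensions
#'
#' The rectangular-plate fish model: a NACA 4-digit symmetric section (chord
#' along the body axis, thickness lateral) extruded vertically over the model
#' height.  Defaults follow the Biwa-salmon model: total model length 0.439 m,
#' height 0.0893 m, maximum section thickness 0.0451 m.  `body_length` (BL,
#' 0.397 m) converts kinematic BL units to metres; model length L is the unit
#' for pair separations.
#'
#' @param length model total length L (m).
#' @param height model height (m).
#' @param max_thickness maximum section thickness (m).
#' @param body_length fish body length BL (m) for kinematic unit conversion.
#' @return An object of class `fish_geometry`.
#' @export
fish_geometry <- function(length = 0.439, height = 0.0893,
                          max_thickness = 0.0451, body_length = 0.397) {
  v <- c(length, height, max_thickness, body_length)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("all dimensions must be positive and finite")
  if (max_thickness >= length) stop("'max_thickness' must be below 'length'")
  structure(list(length = length, height = height,
                 max_thickness = max_thickness, body_length = body_length),
            class = "fish_geometry")
}

#' @export
print.fish_geometry <- function(x, ...) {
  cat(sprintf(paste0("Fish model: L = %.4g m, height = %.4g m, ",
                     "max thickness = %.4g m (BL = %.4g m)\n"),
              x$length, x$height, x$max_thickness, x$body_length))
  invisible(x)
}

#' NACA 4-digit symmetric half-thickness
#'
#' Standard four-digit thickness polynomial with the closed-trailing-edge
#' coefficient (-0.1036), so the half-thickness is exactly zero at both the
#' leading and trailing edges.
#'
#' @param xc chordwise fraction in \[0, 1\]; vectorized.
#' @param t_ratio maximum thickness as a fraction of chord, in (0, 1).
#' @return Half-thickness as a fraction of chord.
#' @export
naca_half_thickness <- function(xc, t_ratio) {
  if (any(!is.finite(xc)) || any(xc < 0) || any(xc > 1))
    stop("'xc' must lie in [0, 1]")
  if (!is.finite(t_ratio) || t_ratio <= 0 || t_ratio >= 1)
    stop("'t_ratio' must lie in (0, 1)")
  5 * t_ratio * (0.2969 * sqrt(xc) - 0.1260 * xc - 0.3516 * xc^2 +
                   0.2843 * xc^3 - 0.1036 * xc^4)
}

## Cosine-clustered chordwise abscissae on [0, L] (dense at both edges).
cosine_spacing <- function(n, L) {
  L * (1 - cos(pi * seq(0, 1, length.out = n + 1))) / 2
}

#' Build the discretized fish-body surface
#'
#' Constant NACA section extruded vertically: side surfaces, plus top and
#' bottom caps, triangulated.  Chordwise nodes are cosine-clustered toward
#' the leading and trailing edges.
#'
#' @param geom a [fish_geometry].
#' @param n_chord number of chordwise panels (>= 10).
#' @param n_span number of vertical (spanwise) panels (>= 2).
#' @return An object of class `fish_body`: `nodes` (N x 3 matrix, m),
#'   `nodes0` (undeformed copy), `elements` (M x 3 node-index matrix),
#'   `areas`, `normals`, `velocities` (N x 3, m/s), `midline_x` (chordwise
#'   stations, m), `geom`.
#' @export
build_fish_body <- function(geom, n_chord = 40, n_span = 8) {
  stopifnot(inherits(geom, "fish_geometry"))
  if (n_chord < 10) stop("'n_chord' must be >= 10")
  if (n_span < 2) stop("'n_span' must be >= 2")
  L <- geom$length; H <- geom$height
  xs <- cosine_spacing(n_chord, L)
  yt <- naca_half_thickness(xs / L, geom$max_thickness / L) * L
  zs <- seq(0, H, length.out = n_span + 1)
  nc <- n_chord + 1

  ## ring of 2*n_chord nodes per z level: upper surface LE->TE then lower
  ## TE->LE, sharing the LE and TE points.
  ring_x <- c(xs, rev(xs[2:(nc - 1)]))
  ring_y <- c(yt, -rev(yt[2:(nc - 1)]))
  m <- length(ring_x)                    # 2 * n_chord
  nodes <- cbind(x = rep(ring_x, times = n_span + 1),
                 y = rep(ring_y, times = n_span + 1),
                 z = rep(zs, each = m))

  tri <- list(); k <- 1L
  idx <- function(level, j) (level - 1L) * m + ((j - 1L) %% m) + 1L
  for (lev in seq_len(n_span)) {
    for (j in seq_len(m)) {
      a <- idx(lev, j); b <- idx(lev, j + 1L)
      cp <- idx(lev + 1L, j + 1L); dp <- idx(lev + 1L, j)
      tri[[k]] <- c(a, cp, b); k <- k + 1L
      tri[[k]] <- c(a, dp, cp); k <- k + 1L
    }
  }
  ## caps: zipper between upper node j and the lower node at the same x
  low_of <- function(j) if (j == 1L || j == nc) j else m - j + 2L
  for (lev in c(1L, n_span + 1L)) {
    for (j in seq_len(nc - 1L)) {
      u1 <- idx(lev, j); u2 <- idx(lev, j + 1L)
      l1 <- idx(lev, low_of(j)); l2 <- idx(lev, low_of(j + 1L))
      quad <- if (lev == 1L) list(c(u1, u2, l2), c(u1, l2, l1))
              else list(c(u1, l2, u2), c(u1, l1, l2))
      for (tr in quad) if (length(unique(tr)) == 3L) {
        tri[[k]] <- tr; k <- k + 1L
      }
    }
  }
  elements <- do.call(rbind, tri)
  body <- structure(list(nodes = nodes, nodes0 = nodes, elements = elements,
                         velocities = matrix(0, nrow(nodes), 3),
                         midline_x = xs, geom = geom, time = 0),
                    class = "fish_body")
  update_body_metrics(body)
}

## Recompute per-element areas and outward normals from current nodes.
update_body_metrics <- function(body) {
  el <- body$elements
  p1 <- body$nodes[el[, 1], , drop = FALSE]
  p2 <- body$nodes[el[, 2], , drop = FALSE]
  p3 <- body$nodes[el[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- sqrt(cx^2 + cy^2 + cz^2)
  keep <- nrm > 1e-300
  body$areas <- nrm / 2
  body$normals <- cbind(cx, cy, cz) / ifelse(keep, nrm, 1)
  body
}

#' @export
print.fish_body <- function(x, ...) {
  cat(sprintf("Fish body surface: %d nodes, %d triangles, area %.4f m^2\n",
              nrow(x$nodes), nrow(x$elements), sum(x$areas)))
  invisible(x)
}

#' Total wetted surface area of a fish body
#'
#' @param body a [fish_body].
#' @return Area in m^2.
#' @export
wetted_area <- function(body) sum(body$areas)

#' Deform the fish body with the body-wave motion
#'
#' Displaces every node laterally by \eqn{h(x/BL, t) \times BL} metres and
#' sets the nodal velocity to the analytic time derivative of that
#' displacement; axial and vertical coordinates are unchanged (pure lateral
#' displacement, the literal definition of the body wave).
#'
#' @param body a [fish_body] (deformation is always applied to the
#'   undeformed reference nodes).
#' @param params a [bodywave_params].
#' @param t time (s).
#' @return The deformed [fish_body] with updated `velocities`, `areas`,
#'   `normals`.
#' @export
deform_body <- function(body, params, t) {
  stopifnot(inherits(body, "fish_body"), inherits(params, "bodywave_params"))
  BL <- body$geom$body_length
  x_bl <- body$nodes0[, 1] / BL
  body$nodes <- body$nodes0
  body$nodes[, 2] <- body$nodes0[, 2] +
    evaluate_displacement(x_bl, t, params) * BL
  body$velocities <- cbind(0, displacement_velocity(x_bl, t, params) * BL, 0)
  body$time <- t
  update_body_metrics(body)
}

#' Export a fish body to Wavefront OBJ (ASCII)
#'
#' @param body a [fish_body].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_body_obj <- function(body, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     body$nodes[, 1], body$nodes[, 2], body$nodes[, 3]), con)
  writeLines(sprintf("f %d %d %d", body$elements[, 1], body$elements[, 2],
                     body$elements[, 3]), con)
  invisible(path)
}

#' Export a fish body to STL (ASCII)
#'
#' @inheritParams write_body_obj
#' @return `path`, invisibly.
#' @export
write_body_stl <- function(body, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid fishbody", con)
  el <- body$elements
  for (i in seq_len(nrow(el))) {
    n <- body$normals[i, ]
    writeLines(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("  outer loop", con)
    for (j in 1:3) {
      p <- body$nodes[el[i, j], ]
      writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid fishbody", con)
  invisible(path)
}

#' Dump fish-body nodes and elements to CSV
#'
#' Writes `<stem>_nodes.csv` (node coordinates and velocities) and
#' `<stem>_elements.csv` (node indices, area, normal).
#'
#' @param body a [fish_body].
#' @param stem output path stem.
#' @return The two paths, invisibly.
#' @export
write_body_csv <- function(body, stem) {
  np <- paste0(stem, "_nodes.csv"); ep <- paste0(stem, "_elements.csv")
  utils::write.csv(data.frame(x = body$nodes[, 1], y = body$nodes[, 2],
                              z = body$nodes[, 3],
                              vx = body$velocities[, 1],
                              vy = body$velocities[, 2],
                              vz = body$velocities[, 3]),
                   np, row.names = FALSE)
  utils::write.csv(data.frame(n1 = body$elements[, 1],
                              n2 = body$elements[, 2],
                              n3 = body$elements[, 3],
                              area = body$areas,
                              nx = body$normals[, 1],
                              ny = body$normals[, 2],
                              nz = body$normals[, 3]),
                   ep, row.names = FALSE)
  invisible(c(np, ep))
}
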