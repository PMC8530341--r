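# Template geometry for the synthetic knee generator.
#
# All templates live in one anatomical frame (right-knee convention):
# axis 1 = medio-lateral (medial = +x for a right knee), axis 2 =
# antero-posterior, axis 3 = inferio-superior, origin near the center of the
# tibial plateau. Units are mm throughout.

# --- mesh primitives -------------------------------------------------------

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times with vertices projected to the unit
#' sphere; outward winding.
#'
#' @param subdiv number of subdivision rounds (0 = plain icosahedron).
#' @return A [surface_mesh()].
#' @keywords internal
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      p <- (vlist[[a]] + vlist[[b]]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      id <- length(vlist)
      mid_cache[[key]] <- id
      id
    }
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4L, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  m <- surface_mesh(v, f)
  if (mesh_enclosed_volume(m) < 0) m <- surface_mesh(v, f[, c(1L, 3L, 2L)])
  m
}

#' Ellipsoid mesh
#'
#' @param semi length-3 semi-axes (mm).
#' @param center length-3 center (mm).
#' @param subdiv icosphere subdivision level.
#' @return A closed [surface_mesh()].
#' @keywords internal
ellipsoid_mesh <- function(semi, center = c(0, 0, 0), subdiv = 3L) {
  m <- icosphere(subdiv)
  v <- sweep(sweep(m$vertices, 2L, semi, "*"), 2L, center, "+")
  surface_mesh(v, m$faces)
}

#' C-shaped meniscal wedge mesh (capped partial torus)
#'
#' A tube with elliptical cross-section swept along a circular arc around
#' `center`, capped with triangle fans at both arc ends. The arc spans
#' `theta` (radians, measured from the +x direction), so the template opens
#' toward the intercondylar region.
#'
#' @param center xy center of the arc (mm); z is the vertical mid-plane.
#' @param z_mid vertical position of the cross-section center (mm).
#' @param radius centerline radius (mm).
#' @param cs_radial,cs_vertical cross-section semi-axes (mm).
#' @param theta length-2 arc angle range (radians).
#' @param nu,nv sweep and cross-section sampling.
#' @return A closed [surface_mesh()].
#' @keywords internal
meniscus_mesh <- function(center, z_mid, radius, cs_radial, cs_vertical,
                          theta, nu = 48L, nv = 16L) {
  us <- seq(theta[1L], theta[2L], length.out = nu)
  phis <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  verts <- matrix(0, nu * nv + 2L, 3L)
  for (i in seq_len(nu)) {
    ct <- cos(us[i]); st <- sin(us[i])
    for (j in seq_len(nv)) {
      r <- radius + cs_radial * cos(phis[j])
      verts[(i - 1L) * nv + j, ] <- c(
        center[1L] + r * ct,
        center[2L] + r * st,
        z_mid + cs_vertical * sin(phis[j])
      )
    }
  }
  c1 <- nu * nv + 1L # centerline point at first arc end
  c2 <- nu * nv + 2L
  verts[c1, ] <- c(center[1L] + radius * cos(us[1L]),
                   center[2L] + radius * sin(us[1L]), z_mid)
  verts[c2, ] <- c(center[1L] + radius * cos(us[nu]),
                   center[2L] + radius * sin(us[nu]), z_mid)
  faces <- list()
  for (i in seq_len(nu - 1L)) {
    for (j in seq_len(nv)) {
      jn <- if (j == nv) 1L else j + 1L
      a <- (i - 1L) * nv + j
      b <- (i - 1L) * nv + jn
      cc <- i * nv + jn
      d <- i * nv + j
      faces[[length(faces) + 1L]] <- c(a, b, cc)
      faces[[length(faces) + 1L]] <- c(a, cc, d)
    }
  }
  for (j in seq_len(nv)) { # caps
    jn <- if (j == nv) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(c1, jn, j)
    faces[[length(faces) + 1L]] <- c(c2, (nu - 1L) * nv + j, (nu - 1L) * nv + jn)
  }
  m <- surface_mesh(verts, do.call(rbind, faces))
  if (mesh_enclosed_volume(m) < 0)
    m <- surface_mesh(verts, m$faces[, c(1L, 3L, 2L)])
  m
}

# --- template anatomy ------------------------------------------------------

#' Geometric parameters of the synthetic knee templates
#'
#' Positions and sizes (mm) of the six template structures, shared between
#' [build_templates()] and the severity deformation model. The medial
#' meniscus outer rim is calibrated to touch the tibial-plateau footprint
#' edge at the central AP row, so the baseline meniscal extrusion is exactly
#' zero and a planted medio-lateral shift is recovered one-to-one.
#'
#' @return Named list of per-structure parameter lists.
#' @export
knee_template_info <- function() {
  list(
    FB = list(semi = c(34, 27, 24), center = c(0, 0, 38),
              condyle_amp = 1.5, condyle_xy = rbind(c(16, -4), c(-16, -4)),
              condyle_sigma = 8,
              bump_sites = rbind(c(32, 0, 22), c(-32, 0, 22)), bump_sigma = 8),
    TB = list(semi = c(36, 28, 25), center = c(0, 0, -27),
              bump_sites = rbind(c(34, 0, -16), c(-34, 0, -16)), bump_sigma = 8),
    FC = list(semi = c(28, 22, 2.0), center = c(0, 0, 10)),
    mTC = list(semi = c(13, 19, 1.25), center = c(16, 0, 1.25)),
    lTC = list(semi = c(13, 19, 1.25), center = c(-16, 0, 1.25)),
    mM = list(center = c(16, 0), z_mid = 5, radius = 15.5,
              cs_radial = 4.5, cs_vertical = 1.5,
              theta = c(-110, 110) * pi / 180),
    lM = list(center = c(-16, 0), z_mid = 5, radius = 15.5,
              cs_radial = 4.5, cs_vertical = 1.5,
              theta = c(70, 290) * pi / 180)
  )
}

#' Build the six template structure meshes
#'
#' Deterministic construction of closed, outward-wound template meshes for
#' femoral/tibial bone (ellipsoids, the femur with two inferior condyle
#' bumps), femoral and tibial cartilages (thin ellipsoidal slabs) and both
#' menisci (C-shaped capped tori resting on the tibial-plateau footprint),
#' in the shared right-knee anatomical frame.
#'
#' @param subdiv icosphere subdivision level for bones and cartilages.
#' @return Named list of six [surface_mesh()] objects
#'   (`FB`, `TB`, `FC`, `mTC`, `lTC`, `mM`, `lM` order as [knee_labels]).
#' @export
build_templates <- function(subdiv = 3L) {
  p <- knee_template_info()
  fb <- ellipsoid_mesh(p$FB$semi, p$FB$center, subdiv)
  # inferior condyle bumps on the femur
  v <- fb$vertices
  lower <- v[, 3L] < p$FB$center[3L]
  for (i in seq_len(nrow(p$FB$condyle_xy))) {
    cxy <- p$FB$condyle_xy[i, ]
    w <- exp(-((v[, 1L] - cxy[1L])^2 + (v[, 2L] - cxy[2L])^2) /
               (2 * p$FB$condyle_sigma^2))
    v[, 3L] <- v[, 3L] - p$FB$condyle_amp * w * lower
  }
  fb <- surface_mesh(v, fb$faces)
  list(
    FB = fb,
    TB = ellipsoid_mesh(p$TB$semi, p$TB$center, subdiv),
    FC = ellipsoid_mesh(p$FC$semi, p$FC$center, subdiv),
    mTC = ellipsoid_mesh(p$mTC$semi, p$mTC$center, max(2L, subdiv - 1L)),
    lTC = ellipsoid_mesh(p$lTC$semi, p$lTC$center, max(2L, subdiv - 1L)),
    mM = meniscus_mesh(p$mM$center, p$mM$z_mid, p$mM$radius,
                       p$mM$cs_radial, p$mM$cs_vertical, p$mM$theta),
    lM = meniscus_mesh(p$lM$center, p$lM$z_mid, p$lM$radius,
                       p$lM$cs_radial, p$lM$cs_vertical, p$lM$theta)
  )
}
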