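# Prior transforms between distance and vergence, and the "internalised"
# prior obtained by passing world distances through the model's
# physical-to-perceived mapping.

#' Vergence prior from a sample of world distances
#'
#' Passes radial distances through the distance-to-vergence transform
#' `theta = atan(h / D)` elementwise. The empirical distribution of the
#' result is the vergence prior an observer would form by fixating those
#' distances.
#'
#' @param distances radial distances from the cyclopean eye, cm (all > 0).
#' @param geom a [viewing_geometry()].
#' @return Angles in (0, pi/2), radians, same length as `distances`.
#' @export
vergence_prior_from_distances <- function(distances, geom = viewing_geometry()) {
  geom <- as_geometry(geom)
  bad <- which(!is.finite(distances) | distances <= 0)
  if (length(bad)) {
    stop_domain(
      "non-positive distance at row(s) %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    )
  }
  atan(geom$h / distances)
}

#' Distance density implied by a flat vergence prior
#'
#' If the prior over the half vergence angle is uniform on `(a, b)`
#' (radians), the implied density over distance is
#' `p(D) = h / (|b - a| * (h^2 + D^2))` on the support
#' `(h / tan(b), h / tan(a))`. With the full domain `a = 0, b = pi/2` the
#' support is all positive distances, the density integrates to one, and
#' it decreases strictly in distance with its maximum toward zero: a flat
#' vergence prior corresponds to near distances being much more probable
#' than far ones.
#'
#' @param d distance(s), cm.
#' @param a,b lower/upper bounds of the uniform vergence prior, radians,
#'   `0 <= a < b <= pi/2`.
#' @param geom a [viewing_geometry()].
#' @return Density values (per cm); zero outside the support.
#' @export
flat_vergence_distance_pdf <- function(d, a = 0, b = pi / 2,
                                       geom = viewing_geometry()) {
  geom <- as_geometry(geom)
  stopifnot(a >= 0, b <= pi / 2, a < b)
  h <- geom$h
  lo <- if (b >= pi / 2) 0 else h / tan(b)
  hi <- if (a <= 0) Inf else h / tan(a)
  out <- h / ((b - a) * (h^2 + d^2))
  out[d <= lo | d >= hi] <- 0
  out
}

#' @param n number of draws.
#' @param seed integer seed.
#' @rdname flat_vergence_distance_pdf
#' @details `rflat_vergence_distance()` samples the density exactly by
#'   drawing uniform angles on `(a, b)` and inverting through
#'   `D = h / tan(theta)`.
#' @export
rflat_vergence_distance <- function(n, a = 0, b = pi / 2,
                                    geom = viewing_geometry(), seed) {
  geom <- as_geometry(geom)
  stopifnot(a >= 0, b <= pi / 2, a < b, n >= 1)
  theta <- with_local_seed(seed, runif(n, a, b))
  geom$h / tan(theta)
}

#' Physical-to-perceived distance mapping
#'
#' Returns a vectorised function mapping physical distance to the model's
#' perceived distance at a given noise level: either the single-posterior
#' peak curve (`method = "map"`, deterministic, default) or a slice
#' through a fitted response-surface of simulated response peaks
#' (`method = "surface"`, pass the [fit_peak_surface()] result via
#' `surface`).
#'
#' @param noise a [vergence_noise()] (or sigma in degrees).
#' @param geom a [viewing_geometry()].
#' @param bounds peak search bounds, cm.
#' @param method `"map"` or `"surface"`.
#' @param surface a `peak_surface`, required for `method = "surface"`.
#' @return A function `f(distance_cm) -> perceived_cm`. For the surface
#'   method, distances outside the surface's fitted span return `NA`.
#' @export
perceived_distance_map <- function(noise, geom = viewing_geometry(),
                                   bounds = c(10, 600),
                                   method = c("map", "surface"),
                                   surface = NULL) {
  noise <- as_noise(noise)
  geom <- as_geometry(geom)
  method <- match.arg(method)
  if (method == "map") {
    force(bounds)
    function(d) {
      map_peak_vec(half_vergence(geom, d), noise$sigma, geom$h, bounds)
    }
  } else {
    if (!inherits(surface, "peak_surface")) {
      stop_domain("method = \"surface\" requires a fitted peak_surface")
    }
    dr <- surface$distance_range
    s <- noise$sigma_deg
    function(d) {
      out <- rep(NA_real_, length(d))
      ok <- d >= dr[1] & d <= dr[2]
      out[ok] <- predict(surface, s, d[ok])
      out
    }
  }
}

#' Internalised distance prior
#'
#' Passes a sample of world distances through a physical-to-perceived
#' mapping, yielding the distribution of distances the observer would
#' internalise. Under the model's peak mapping, far distances are
#' compressed toward near ones: the upper quantiles and the mean of the
#' output fall below those of the input. Rows where the mapping is
#' undefined (`NA`) are dropped; the count of dropped rows is attached as
#' attribute `"dropped"`.
#'
#' @param distances world distances, cm (all > 0).
#' @param mapping a function `f(distance) -> perceived distance`, e.g.
#'   from [perceived_distance_map()]; the identity function leaves the
#'   sample unchanged.
#' @return Numeric vector of perceived distances.
#' @export
internalise_prior <- function(distances, mapping) {
  check_positive(distances, "distances")
  stopifnot(is.function(mapping))
  out <- mapping(distances)
  dropped <- sum(!is.finite(out))
  if (dropped > 0) {
    message(sprintf("internalise_prior: dropped %d unmappable distances", dropped))
  }
  out <- out[is.finite(out)]
  attr(out, "dropped") <- dropped
  out
}

# ---- synthetic scene sampler -------------------------------------------

# Squared distance from sphere centre `cen` to the segment e -> p,
# vectorised over points (rows of p).
segment_occludes <- function(e, p, cen, r) {
  dx <- p[, 1] - e[1]
  dy <- p[, 2] - e[2]
  dz <- p[, 3] - e[3]
  len2 <- dx^2 + dy^2 + dz^2
  t <- ((cen[1] - e[1]) * dx + (cen[2] - e[2]) * dy + (cen[3] - e[3]) * dz) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- e[1] + t * dx - cen[1]
  qy <- e[2] + t * dy - cen[2]
  qz <- e[3] + t * dz - cen[3]
  qx^2 + qy^2 + qz^2 < (r - 1e-9)^2
}

place_spheres <- function(n_objects, radius_range, plane_side,
                          max_place_attempts) {
  half <- plane_side / 2
  cx <- cz <- r <- numeric(0)
  for (i in seq_len(n_objects)) {
    placed <- FALSE
    for (a in seq_len(max_place_attempts)) {
      ri <- runif(1, radius_range[1], radius_range[2])
      xi <- runif(1, -half + ri, half - ri)
      zi <- runif(1, -half + ri, half - ri)
      if (!length(cx) || all((cx - xi)^2 + (cz - zi)^2 > (r + ri)^2)) {
        cx <- c(cx, xi); cz <- c(cz, zi); r <- c(r, ri)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL) # scene discarded, caller retries
  }
  cbind(x = cx, y = r, z = cz, r = r) # spheres rest on the floor plane
}

#' Sample radial distances from a synthetic cluttered scene
#'
#' A simplified stand-in for a natural-scene distance sample: `n_objects`
#' spheres are placed sequentially on a square floor plane by rejection of
#' intersecting bounding circles (scenes where placement fails are
#' discarded and retried, up to `max_scene_attempts`). Surface points are
#' sampled uniformly on each sphere and kept only if visible to *both*
#' eyes (front-facing on their own sphere and not occluded by any other
#' sphere along the eye-to-point segment). The returned values are the
#' radial distances of visible points from the cyclopean eye.
#'
#' The default layout mirrors a tabletop arrangement: a 35 cm square
#' plane, observer eyes at height 8 cm and 60 cm back from the plane
#' centre, interocular 6.5 cm.
#'
#' @param n_objects number of spheres (0 gives an empty sample).
#' @param radius_range sphere radius range, cm.
#' @param n_points surface points sampled per sphere before visibility
#'   culling.
#' @param n_scenes number of independent scenes to pool.
#' @param plane_side side length of the square floor plane, cm.
#' @param observer cyclopean-eye position `c(x, y, z)` relative to the
#'   plane centre, cm.
#' @param geom a [viewing_geometry()].
#' @param seed integer seed.
#' @param max_scene_attempts retry budget for discarded scenes.
#' @param max_place_attempts per-object placement attempts within a scene.
#' @return Radial distances (cm) of all both-eye-visible sampled points,
#'   pooled over scenes.
#' @export
synthetic_scene_distances <- function(n_objects = 14, radius_range = c(2, 6),
                                      n_points = 200L, n_scenes = 1L,
                                      plane_side = 35,
                                      observer = c(0, 8, 60),
                                      geom = viewing_geometry(), seed,
                                      max_scene_attempts = 100L,
                                      max_place_attempts = 200L) {
  geom <- as_geometry(geom)
  stopifnot(n_objects >= 0, n_points >= 1, n_scenes >= 1)
  if (n_objects == 0L) return(numeric(0))
  if (2 * radius_range[2] > plane_side) {
    stop_domain("objects too large for the plane; use fewer/smaller objects")
  }
  h <- geom$h
  eye_l <- observer + c(-h, 0, 0)
  eye_r <- observer + c(h, 0, 0)
  with_local_seed(seed, {
    all_d <- vector("list", n_scenes)
    for (sc in seq_len(n_scenes)) {
      spheres <- NULL
      for (a in seq_len(max_scene_attempts)) {
        spheres <- place_spheres(n_objects, radius_range, plane_side,
                                 max_place_attempts)
        if (!is.null(spheres)) break
      }
      if (is.null(spheres)) {
        stop_domain(
          "could not place %d objects after %d scene attempts; try fewer or smaller objects",
          n_objects, max_scene_attempts
        )
      }
      pts <- do.call(rbind, lapply(seq_len(nrow(spheres)), function(i) {
        # uniform points on the sphere via normalised Gaussian triples
        g <- matrix(rnorm(3 * n_points), ncol = 3)
        g <- g / sqrt(rowSums(g^2))
        p <- sweep(g * spheres[i, "r"], 2, spheres[i, c("x", "y", "z")], `+`)
        cbind(p, sphere = i)
      }))
      visible_from <- function(eye) {
        to_eye <- -sweep(pts[, 1:3, drop = FALSE], 2, eye, `-`) # eye - p
        normal <- pts[, 1:3, drop = FALSE] -
          spheres[pts[, 4], c("x", "y", "z"), drop = FALSE] # p - centre
        facing <- rowSums(normal * to_eye) > 0
        occ <- rep(FALSE, nrow(pts))
        for (j in seq_len(nrow(spheres))) {
          cand <- pts[, 4] != j & !occ
          if (!any(cand)) next
          occ[cand] <- segment_occludes(
            eye, pts[cand, 1:3, drop = FALSE],
            spheres[j, c("x", "y", "z")], spheres[j, "r"]
          )
        }
        facing & !occ
      }
      vis <- visible_from(eye_l) & visible_from(eye_r)
      kept <- pts[vis, 1:3, drop = FALSE]
      all_d[[sc]] <- sqrt(rowSums(sweep(kept, 2, observer, `-`)^2))
    }
    unlist(all_d)
  })
}
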