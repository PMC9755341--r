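# Synthetic anterior-view thoracic MIBG phantom.
#
# The phantom composites simple geometric organs onto a soft-tissue
# background: two elliptical lung fields (photopenic relative to soft
# tissue), a mediastinal strip between their medial contours, a myocardial
# annulus around a lower-intensity left-ventricular cavity, a basal/outflow
# myocardial segment extending toward the cardiac base (its uptake scales
# with myocardial uptake, which is what the fixed-size cardiac oval placed
# inside the landmark square predominantly samples), and a hepatic
# half-ellipse.  The late image applies organ-specific washout factors to
# the expected-count map before an independent Poisson draw.  All geometry
# is expressed in 256-pixel reference units and scaled with `matrix_size`.

#' Phantom parameters
#'
#' @param matrix_size Image side in pixels (>= 64; default 256).
#' @param lambda_background,lambda_lung,lambda_mediastinum,lambda_myocardium,lambda_cavity,lambda_liver
#'   Expected counts per pixel of each organ at acquisition scale 1.  The
#'   lung rate must stay below the mediastinal rate so that the medial lung
#'   contours are detectable.
#' @param basal_fraction Uptake of the basal/outflow myocardial segment as a
#'   fraction of `lambda_myocardium` (default 0.6).
#' @param acquisition_scale Global count multiplier (default 1).
#' @param washout Named list of per-organ multiplicative factors in (0, 1.5]
#'   applied to the late expected-count map (the basal segment follows the
#'   myocardium).
#' @param poisson_noise Draw Poisson counts (`TRUE`, default) or return the
#'   exact expectation maps.
#' @param geometry Named list of organ geometries in 256-reference pixel
#'   units; see Details.  Override only entries you need.
#' @param flip Mirror the anterior-view display convention (heart on the
#'   image left instead of right).
#' @details Geometry entries are lists with `c` (center, x/y) and `a`
#'   (semi-axes) for `lung_left`, `lung_right`, `heart` (plus scalar `wall`,
#'   the myocardial wall thickness in pixels) , `basal` and `liver`.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(matrix_size = 256L,
                           lambda_background = 5,
                           lambda_lung = 3,
                           lambda_mediastinum = 6,
                           lambda_myocardium = 18,
                           lambda_cavity = 8,
                           lambda_liver = 12,
                           basal_fraction = 0.6,
                           acquisition_scale = 1,
                           washout = list(background = 0.90, lung = 0.85,
                                          mediastinum = 0.90,
                                          myocardium = 0.85, cavity = 0.80,
                                          liver = 0.80),
                           poisson_noise = TRUE,
                           geometry = list(),
                           flip = FALSE) {
  lam <- c(background = lambda_background, lung = lambda_lung,
           mediastinum = lambda_mediastinum, myocardium = lambda_myocardium,
           cavity = lambda_cavity, liver = lambda_liver)
  if (anyNA(lam) || any(lam < 0)) {
    stop_mibg("mibg_params", "all expected-count rates must be >= 0")
  }
  if (!(lambda_lung < lambda_mediastinum)) {
    stop_mibg("mibg_params",
              "lambda_lung must be < lambda_mediastinum (landmark detectability)")
  }
  if (!is_count_scalar(matrix_size) || matrix_size < 64) {
    stop_mibg("mibg_params", "matrix_size must be an integer >= 64")
  }
  if (!(acquisition_scale > 0)) {
    stop_mibg("mibg_params", "acquisition_scale must be positive")
  }
  if (!(basal_fraction >= 0)) {
    stop_mibg("mibg_params", "basal_fraction must be >= 0")
  }
  wdef <- list(background = 0.90, lung = 0.85, mediastinum = 0.90,
               myocardium = 0.85, cavity = 0.80, liver = 0.80)
  washout <- utils::modifyList(wdef, as.list(washout))
  wv <- unlist(washout[names(wdef)])
  if (any(wv <= 0 | wv > 1.5)) {
    stop_mibg("mibg_params", "washout factors must lie in (0, 1.5]")
  }
  gdef <- list(
    lung_left = list(c = c(80, 108), a = c(34, 52)),
    lung_right = list(c = c(178, 108), a = c(36, 52)),
    heart = list(c = c(158, 152), a = c(44, 32), wall = 10),
    basal = list(c = c(150, 104), a = c(24, 20)),
    liver = list(c = c(84, 196), a = c(46, 26))
  )
  geometry <- utils::modifyList(gdef, as.list(geometry))
  s <- matrix_size / 256
  for (org in names(geometry)) {
    g <- geometry[[org]]
    bb <- c(g$c[1] - g$a[1], g$c[1] + g$a[1], g$c[2] - g$a[2], g$c[2] + g$a[2]) * s
    if (org != "liver" && (any(bb < 0) || any(bb > matrix_size - 1))) {
      stop_mibg("mibg_params", "organ '%s' extends beyond the image", org)
    }
  }
  structure(
    list(matrix_size = as.integer(matrix_size),
         lambda = as.list(lam), basal_fraction = basal_fraction,
         acquisition_scale = acquisition_scale, washout = washout,
         poisson_noise = isTRUE(poisson_noise), geometry = geometry,
         flip = isTRUE(flip)),
    class = "phantom_params"
  )
}

ellipse_mask <- function(n, cx, cy, rx, ry, lower_half = FALSE) {
  x <- (seq_len(n) - 1 - cx) / rx
  y <- (seq_len(n) - 1 - cy) / ry
  m <- outer(y^2, x^2, `+`) <= 1
  if (lower_half) m[seq_len(n) - 1 < cy, ] <- FALSE
  m
}

# rasterized organ masks plus derived landmark geometry; computed once per
# parameter set and reused across a cohort
build_phantom_geometry <- function(params) {
  n <- params$matrix_size
  s <- n / 256
  g <- lapply(params$geometry, function(e) {
    out <- list(c = e$c * s, a = e$a * s)
    if (!is.null(e$wall)) out$wall <- e$wall * s
    out
  })
  if (params$flip) {
    for (org in names(g)) g[[org]]$c[1] <- (n - 1) - g[[org]]$c[1]
    tmp <- g$lung_left; g$lung_left <- g$lung_right; g$lung_right <- tmp
  }
  em <- function(e, lower_half = FALSE) {
    ellipse_mask(n, e$c[1], e$c[2], e$a[1], e$a[2], lower_half)
  }
  lungL <- em(g$lung_left)
  lungR <- em(g$lung_right)
  heart_outer <- em(g$heart)
  cavity <- ellipse_mask(n, g$heart$c[1], g$heart$c[2],
                         max(g$heart$a[1] - g$heart$wall, 1),
                         max(g$heart$a[2] - g$heart$wall, 1))
  basal <- em(g$basal)
  liver <- em(g$liver, lower_half = TRUE)

  left_edge <- max(which(apply(lungL, 2, any))) - 1
  right_edge <- min(which(apply(lungR, 2, any))) - 1
  lung_rows <- which(apply(lungL | lungR, 1, any))
  med <- matrix(FALSE, n, n)
  med[min(lung_rows):max(lung_rows),
      (left_edge + 2):(right_edge)] <- TRUE # columns strictly between edges
  med <- med & !(lungL | lungR)

  myo <- heart_outer & !cavity
  if (!any(myo)) {
    stop_mibg("mibg_geometry", "myocardium mask is empty")
  }
  # the landmark square is defined on what an operator sees: lung fields as
  # painted (higher-uptake structures overwrite them), medial contours taken
  # over the upper-thorax rows between the apexes and the cardiac border
  over <- basal | liver | heart_outer
  lungL_eff <- lungL & !over
  lungR_eff <- lungR & !over
  top <- min(which(apply(lungL_eff | lungR_eff, 1, any))) - 1
  bottom <- min(which(apply(heart_outer, 1, any))) - 1
  thorax <- (top + 1):(bottom + 1)
  lsel <- lungL_eff[thorax, , drop = FALSE]
  rsel <- lungR_eff[thorax, , drop = FALSE]
  if (!any(lsel) || !any(rsel)) {
    stop_mibg("mibg_geometry", "lung fields do not span the upper thorax")
  }
  square <- landmark_square(
    top = top, bottom = bottom,
    left = max(which(apply(lsel, 2, any))) - 1,
    right = min(which(apply(rsel, 2, any))) - 1
  )

  theta <- 2 * pi * (seq_len(24) - 1) / 24
  contour <- polygon_roi(
    x = g$heart$c[1] + g$heart$a[1] * cos(theta),
    y = g$heart$c[2] + g$heart$a[2] * sin(theta)
  )

  geom <- list(n = n, masks = list(lung = lungL | lungR, mediastinum = med,
                                   basal = basal, liver = liver,
                                   myocardium = myo, cavity = cavity),
               square = square, contour = contour)

  # cache the ground-truth ROI masks and an exclusive-region overlap table
  # so per-subject ground truth is pure arithmetic (the cohort generator
  # reuses one geometry across all subjects)
  placed <- place_semiautomatic_rois(square)
  card_mask <- rasterize(contour, c(n, n))
  med_mask <- rasterize(placed$mediastinal, c(n, n))
  if (any(card_mask & med_mask)) {
    stop_mibg("mibg_geometry",
              "ground-truth cardiac and mediastinal masks overlap")
  }
  ms <- geom$masks
  excl <- list(
    cavity = ms$cavity,
    myocardium = ms$myocardium,
    liver = ms$liver & !(ms$myocardium | ms$cavity),
    basal = ms$basal & !(ms$liver | ms$myocardium | ms$cavity),
    mediastinum = ms$mediastinum &
      !(ms$basal | ms$liver | ms$myocardium | ms$cavity),
    lung = ms$lung & !(ms$basal | ms$liver | ms$myocardium | ms$cavity)
  )
  excl$background <- Reduce(`&`, lapply(excl, `!`))
  overlap <- vapply(excl, function(r) {
    c(card = sum(r & card_mask), med = sum(r & med_mask))
  }, numeric(2))
  geom$truth_rois <- list(mediastinal_rect = placed$mediastinal,
                          cardiac_mask = card_mask, mediastinal_mask = med_mask)
  geom$overlap <- overlap
  geom$roi_npix <- c(card = sum(card_mask), med = sum(med_mask))
  geom
}

# expected ROI means from the overlap table; exact for the composited map
expected_roi_means <- function(geom, params, phase,
                               lambda_myocardium = NULL) {
  lam <- params$lambda
  if (!is.null(lambda_myocardium)) lam$myocardium <- lambda_myocardium
  lam$basal <- params$basal_fraction * lam$myocardium
  w <- params$washout
  w$basal <- w$myocardium
  orgs <- colnames(geom$overlap)
  lv <- vapply(orgs, function(o) {
    if (phase == "late") lam[[o]] * w[[o]] else lam[[o]]
  }, numeric(1))
  card <- sum(lv * geom$overlap["card", ]) / geom$roi_npix[["card"]]
  med <- sum(lv * geom$overlap["med", ]) / geom$roi_npix[["med"]]
  c(card = card, med = med) * params$acquisition_scale
}

# geometry cache: cohort-scale callers rebuild identical geometry otherwise
.geom_cache <- new.env(parent = emptyenv())

cached_geometry <- function(params) {
  u <- unlist(params, use.names = TRUE)
  key <- paste(names(u), u, sep = "=", collapse = ";")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  geom <- build_phantom_geometry(params)
  if (length(ls(.geom_cache)) > 8L) {
    rm(list = ls(.geom_cache), envir = .geom_cache)
  }
  .geom_cache[[key]] <- geom
  geom
}

compose_map <- function(geom, params, phase = c("early", "late"),
                        lambda_myocardium = NULL) {
  phase <- match.arg(phase)
  lam <- params$lambda
  if (!is.null(lambda_myocardium)) lam$myocardium <- lambda_myocardium
  lam$basal <- params$basal_fraction * lam$myocardium
  w <- params$washout
  w$basal <- w$myocardium
  f <- function(org) {
    if (phase == "late") lam[[org]] * w[[org]] else lam[[org]]
  }
  m <- matrix(f("background"), geom$n, geom$n)
  # paint order matters: later organs overwrite earlier ones
  for (org in c("lung", "mediastinum", "basal", "liver", "myocardium",
                "cavity")) {
    m[geom$masks[[org]]] <- f(org)
  }
  m * params$acquisition_scale
}

ground_truth_from_geom <- function(geom, params, lambda_myocardium = NULL) {
  e <- expected_roi_means(geom, params, "early", lambda_myocardium)
  l <- expected_roi_means(geom, params, "late", lambda_myocardium)
  if (e[["med"]] <= 0 || l[["med"]] <= 0) {
    stop_mibg("mibg_geometry", "mediastinal reference region has zero uptake")
  }
  structure(
    list(square = geom$square, cardiac_polygon = geom$contour,
         mediastinal_rect = geom$truth_rois$mediastinal_rect,
         cardiac_mask = geom$truth_rois$cardiac_mask,
         mediastinal_mask = geom$truth_rois$mediastinal_mask,
         true_early_hm = e[["card"]] / e[["med"]],
         true_late_hm = l[["card"]] / l[["med"]],
         lambda_myocardium = lambda_myocardium %||%
           params$lambda$myocardium),
    class = "ground_truth"
  )
}

#' Generate one synthetic phantom (early/late image pair with ground truth)
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed (the generator is a pure function of
#'   `(params, seed)`).
#' @param subject Optional subject id attached to the images.
#' @return List with elements `early` and `late` ([planar_image()]s) and
#'   `truth` (the noise-free ground truth: landmark square, true cardiac
#'   contour polygon and mediastinal rectangle, their masks, and the true
#'   early/late H/M ratios).
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L,
                             subject = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  geom <- cached_geometry(params)
  generate_phantom_from_geom(geom, params, seed, subject)
}

generate_phantom_from_geom <- function(geom, params, seed, subject = NULL,
                                       lambda_myocardium = NULL) {
  truth <- ground_truth_from_geom(geom, params, lambda_myocardium)
  early_map <- compose_map(geom, params, "early", lambda_myocardium)
  late_map <- compose_map(geom, params, "late", lambda_myocardium)
  if (params$poisson_noise) {
    counts <- with_seed(derive_seed(seed, 101L), {
      e <- matrix(stats::rpois(length(early_map), early_map),
                  nrow(early_map))
      l <- matrix(stats::rpois(length(late_map), late_map),
                  nrow(late_map))
      list(e, l)
    })
    early_map <- counts[[1]]
    late_map <- counts[[2]]
  }
  list(
    early = planar_image(early_map, "early", subject = subject),
    late = planar_image(late_map, "late", subject = subject),
    truth = truth
  )
}

#' Solve the myocardial uptake rate that yields a target true H/M ratio
#'
#' Both ground-truth ROI means are affine in `lambda_myocardium` (the basal
#' segment scales with it, the cavity does not; at small matrix sizes the
#' mediastinal rectangle may clip the basal segment), so the rate producing
#' a requested noise-free early H/M ratio has a closed form.
#'
#' @param params A [phantom_params()].
#' @param target_hm Desired true early H/M ratio(s) (> 0); vectorized.
#' @param geom Optional precomputed geometry (internal use).
#' @return The `lambda_myocardium` value(s).
#' @export
solve_uptake <- function(params, target_hm, geom = NULL) {
  stopifnot(all(target_hm > 0))
  if (is.null(geom)) geom <- cached_geometry(params)
  e0 <- expected_roi_means(geom, params, "early", lambda_myocardium = 0)
  e1 <- expected_roi_means(geom, params, "early", lambda_myocardium = 1)
  c0 <- e0[["card"]]; c1 <- e1[["card"]] - c0
  m0 <- e0[["med"]]; m1 <- e1[["med"]] - m0
  # h = (c0 + c1 L) / (m0 + m1 L)
  lam <- (target_hm * m0 - c0) / (c1 - target_hm * m1)
  if (any(!is.finite(lam) | lam <= 0)) {
    stop_mibg("mibg_params",
              "target H/M %.3f is not attainable with this geometry",
              target_hm[which(!is.finite(lam) | lam <= 0)[1L]])
  }
  lam
}

#' Default cohort uptake specification
#'
#' Log-normal distribution of the myocardial uptake rate, centered between
#' the uptake levels at which the manual and the semi-automatic method cross
#' their early pathological cut-offs, so a default cohort spans both
#' boundaries (most subjects pathological, as in clinical PD series).
#'
#' @return A list understood by [generate_cohort()].
#' @export
default_hm_spec <- function() {
  list(kind = "uptake", meanlog = log(20), sdlog = 0.40)
}

draw_uptake <- function(hm_spec, n, params, geom) {
  kind <- hm_spec$kind %||% "uptake"
  if (kind == "uptake") {
    if (!is.null(hm_spec$value)) return(rep(hm_spec$value, n))
    stats::rlnorm(n, hm_spec$meanlog %||% log(20), hm_spec$sdlog %||% 0.40)
  } else if (kind == "hm") {
    targets <- if (!is.null(hm_spec$value)) {
      rep(hm_spec$value, n)
    } else {
      mu <- hm_spec$mean %||% 1.9
      sd <- hm_spec$sd %||% 0.4
      lo <- hm_spec$min %||% 1.05
      hi <- hm_spec$max %||% 3.5
      pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)
    }
    solve_uptake(params, targets, geom = geom)
  } else {
    stop_mibg("mibg_argument", "unknown hm_spec kind: %s", kind)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each subject gets an independent early/late phantom pair; the myocardial
#' uptake rate (hence the true H/M ratio) and the myocardial washout factor
#' vary across subjects.
#'
#' @param n Number of subjects (default 35).
#' @param hm_spec Distribution of true cardiac uptake.  Either
#'   `list(kind = "uptake", meanlog =, sdlog =)` (log-normal rate;
#'   `value =` for a point mass) or `list(kind = "hm", mean =, sd =, min =,
#'   max =)` (truncated normal on the true early H/M scale; `value =` for a
#'   point mass, converted to a rate via [solve_uptake()]).
#' @param params A [phantom_params()].
#' @param seed Master seed; subjects use derived per-subject streams, so
#'   growing the cohort never perturbs earlier subjects.
#' @param washout_spec Truncated-normal spec for the per-subject myocardial
#'   washout factor: `list(mean = 0.85, sd = 0.06, min = 0.6, max = 1.05)`.
#' @return List of cohort records, each with `subject`, `early`, `late`,
#'   `truth`.
#' @export
generate_cohort <- function(n = 35L, hm_spec = default_hm_spec(),
                            params = phantom_params(), seed = 1L,
                            washout_spec = list(mean = 0.85, sd = 0.06,
                                                min = 0.60, max = 1.05)) {
  if (!is_count_scalar(n)) {
    stop_mibg("mibg_argument", "n must be a positive integer")
  }
  geom <- cached_geometry(params)
  lambdas <- with_seed(derive_seed(seed, 7L), {
    lam <- draw_uptake(hm_spec, n, params, geom)
    w <- stats::rnorm(n, washout_spec$mean, washout_spec$sd)
    w <- pmin(pmax(w, washout_spec$min), washout_spec$max)
    list(lam = lam, w = w)
  })
  if (any(lambdas$lam <= 0)) {
    stop_mibg("mibg_argument", "hm_spec produced non-positive uptake rates")
  }
  lapply(seq_len(n), function(i) {
    p_i <- params
    p_i$washout$myocardium <- lambdas$w[i]
    rec <- generate_phantom_from_geom(
      geom, p_i, seed = derive_seed(seed, 1L, i),
      subject = sprintf("S%03d", i),
      lambda_myocardium = lambdas$lam[i]
    )
    rec$subject <- sprintf("S%03d", i)
    class(rec) <- "cohort_record"
    rec
  })
}

#' Rater profile
#'
#' Operator-variability model for a simulated rater: Gaussian jitter on the
#' landmark-square coordinates (semi-automatic method), on the cardiac
#' polygon vertices and on the mediastinal rectangle position/size (manual
#' method).
#'
#' @param label Rater label (`"expert"`, `"moderate"`, `"inexpert"` or free
#'   text).
#' @param sigma_landmark SD (pixels) of landmark-coordinate jitter.
#' @param sigma_vertex SD (pixels) of polygon-vertex jitter.
#' @param sigma_rect_pos SD (pixels) of the manual mediastinal rectangle
#'   position.
#' @param sigma_rect_size SD (log scale) of the relative size jitter of the
#'   manual mediastinal rectangle.
#' @return An object of class `rater_profile`.
#' @export
rater_profile <- function(label, sigma_landmark, sigma_vertex,
                          sigma_rect_pos = sigma_landmark,
                          sigma_rect_size = 0.05) {
  s <- c(sigma_landmark, sigma_vertex, sigma_rect_pos, sigma_rect_size)
  if (anyNA(s) || any(s < 0)) {
    stop_mibg("mibg_params", "rater sigmas must be >= 0")
  }
  structure(
    list(label = as.character(label), sigma_landmark = sigma_landmark,
         sigma_vertex = sigma_vertex, sigma_rect_pos = sigma_rect_pos,
         sigma_rect_size = sigma_rect_size),
    class = "rater_profile"
  )
}

#' Default rater profiles (expert, moderate, inexpert)
#'
#' Jitter magnitudes increase with inexperience; the semi-automatic
#' landmark jitter of each rater is smaller than their manual vertex jitter,
#' reflecting the partial automation of the fixed-size method.  The manual
#' mediastinal rectangle, whose size and position are entirely
#' operator-chosen, carries the largest jitter: free placement along the
#' mediastinum is the dominant manual variability source that fixed-size
#' landmark-guided placement removes.
#'
#' @return Named list of three [rater_profile()]s.
#' @export
default_rater_profiles <- function() {
  list(
    expert = rater_profile("expert", sigma_landmark = 0.5, sigma_vertex = 1,
                           sigma_rect_pos = 2, sigma_rect_size = 0.05),
    moderate = rater_profile("moderate", sigma_landmark = 1, sigma_vertex = 2,
                             sigma_rect_pos = 4, sigma_rect_size = 0.10),
    inexpert = rater_profile("inexpert", sigma_landmark = 2, sigma_vertex = 4,
                             sigma_rect_pos = 8, sigma_rect_size = 0.20)
  )
}

#' Simulate a rater's ROI placement on a cohort record
#'
#' @param record A cohort record from [generate_cohort()] or
#'   [generate_phantom()].
#' @param profile A [rater_profile()].
#' @param method `"manual"` (jittered cardiac contour polygon + jittered
#'   mediastinal rectangle) or `"semiautomatic"` (fixed-size ROI pair placed
#'   from the jittered landmark square).
#' @param seed Integer seed.
#' @return An ROI set: list with `cardiac`, `mediastinal`, `method`,
#'   `rater`.
#' @export
simulate_rater_rois <- function(record, profile,
                                method = c("semiautomatic", "manual"),
                                seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "rater_profile"))
  truth <- record$truth
  img_dim <- dim(record$early$counts)
  if (method == "semiautomatic") {
    sq <- truth$square
    out <- with_seed(derive_seed(seed, 11L), {
      j <- stats::rnorm(4L, 0, profile$sigma_landmark)
      sq2 <- tryCatch(
        landmark_square(sq$top + j[1L], sq$bottom + j[2L],
                        sq$left + j[3L], sq$right + j[4L]),
        mibg_invalid_roi = function(e) {
          stop_mibg("mibg_placement", "jittered landmark square degenerated")
        }
      )
      place_semiautomatic_rois(sq2)
    })
    rois <- list(cardiac = out$cardiac, mediastinal = out$mediastinal)
  } else {
    poly <- truth$cardiac_polygon
    rect <- truth$mediastinal_rect
    rois <- with_seed(derive_seed(seed, 13L), {
      nv <- length(poly$x)
      vx <- poly$x + stats::rnorm(nv, 0, profile$sigma_vertex)
      vy <- poly$y + stats::rnorm(nv, 0, profile$sigma_vertex)
      # re-order by angle around the centroid: keeps the drawn contour a
      # simple (star-shaped) polygon even under heavy jitter
      ang <- atan2(vy - mean(vy), vx - mean(vx))
      ord <- order(ang)
      i0 <- which(ord == 1L)
      ord <- ord[c(i0:nv, seq_len(i0 - 1L))]
      dpos <- stats::rnorm(2L, 0, profile$sigma_rect_pos)
      dsz <- stats::rnorm(2L, 0, profile$sigma_rect_size)
      w2 <- max(1L, as.integer(round(rect$w * exp(dsz[1L]))))
      h2 <- max(1L, as.integer(round(rect$h * exp(dsz[2L]))))
      cx <- rect$x0 + rect$w / 2 + dpos[1L]
      cy <- rect$y0 + rect$h / 2 + dpos[2L]
      list(
        cardiac = polygon_roi(vx[ord], vy[ord]),
        mediastinal = rect_roi(floor(cx - w2 / 2 + 0.5),
                               floor(cy - h2 / 2 + 0.5), w2, h2)
      )
    })
  }
  for (role in c("cardiac", "mediastinal")) {
    if (!roi_overlaps_image(rois[[role]], img_dim)) {
      stop_mibg("mibg_placement", "%s ROI fell outside the image", role)
    }
  }
  list(cardiac = rois$cardiac, mediastinal = rois$mediastinal,
       method = method, rater = profile$label)
}

#' Write a cohort to a directory
#'
#' One image file per subject and phase plus a JSON ground-truth sidecar
#' (landmark square, true ROIs, true H/M ratios).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format Image dialect, `"text"` or `"dicom"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("text", "dicom")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "text") "tsv" else "dcm"
  for (rec in cohort) {
    id <- rec$subject
    write_planar(rec$early, file.path(dir, sprintf("%s_early.%s", id, ext)),
                 format)
    write_planar(rec$late, file.path(dir, sprintf("%s_late.%s", id, ext)),
                 format)
    tr <- rec$truth
    jsonlite::write_json(
      list(subject = id,
           square = tr$square[c("top", "bottom", "left", "right")],
           cardiac_polygon = list(x = tr$cardiac_polygon$x,
                                  y = tr$cardiac_polygon$y),
           mediastinal_rect = roi_to_list(tr$mediastinal_rect),
           true_early_hm = tr$true_early_hm,
           true_late_hm = tr$true_late_hm,
           lambda_myocardium = tr$lambda_myocardium),
      file.path(dir, sprintf("%s_truth.json", id)),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
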