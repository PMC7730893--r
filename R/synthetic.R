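#' Configuration for the synthetic plum generator
#'
#' The generator emulates the imaging setup the pipeline expects: a single
#' ellipsoidal, green-toned fruit with radial shading on a near-black
#' background, photographed under ring lighting. Each class paints its own
#' defect morphology: `rot` one large irregular dark-brown region (at least
#' 8\% of the fruit area), `scar` one or two sharp-edged dark patches
#' (2--6\% each), `crack` one thin dark polyline (width at most 3 px),
#' `spot` 12--40 small dark speckles (each well under 0.3\% of the fruit
#' area), `normal` clean skin.
#'
#' @param image_size Edge length of the square output image (default 256).
#' @param background_level 8-bit background intensity (default 18).
#' @param stem_probability Probability of painting a small stem stub
#'   (default 0; the stub reproduces a known confusion between stems and
#'   scar-like defects when enabled).
#' @param seed Integer master seed; together with the class and image index
#'   it fully determines every image.
#' @param class_params Optional list overriding per-class morphology
#'   parameters (see the source for the available fields).
#' @return Object of class `plum_generator_config`.
#' @export
generator_config <- function(image_size = 256, background_level = 18,
                             stem_probability = 0, seed = 1,
                             class_params = list()) {
  if (image_size < 64) stop("image_size must be at least 64")
  if (stem_probability < 0 || stem_probability > 1) {
    stop("stem_probability must lie in [0, 1]")
  }
  defaults <- list(
    rot   = list(area_frac = c(0.10, 0.16), color = c(72, 48, 30)),
    scar  = list(n = c(1, 2), area_frac = c(0.02, 0.06),
                 color = c(70, 60, 40)),
    crack = list(length_frac = c(0.8, 1.3), width = c(2, 3),
                 color = c(35, 30, 22)),
    spot  = list(n = c(12, 40), radius = c(2.5, 4.5), color = c(55, 48, 35))
  )
  for (cls in names(class_params)) {
    defaults[[cls]][names(class_params[[cls]])] <- class_params[[cls]]
  }
  structure(list(image_size = image_size,
                 background_level = background_level,
                 stem_probability = stem_probability,
                 seed = as.integer(seed),
                 class_params = defaults),
            class = "plum_generator_config")
}

# run code under a derived, reproducible RNG state without touching the
# caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

derive_seed <- function(seed, cls, index) {
  ci <- match(cls, defect_classes())
  as.integer((as.numeric(seed) * 100003 + ci * 7919 + index * 104729) %%
               .Machine$integer.max)
}

#' Generate one synthetic plum image
#'
#' Fully determined by `(cfg$seed, cls, index)`: the same triple always
#' yields byte-identical pixels.
#'
#' @param cls One of [defect_classes()].
#' @param cfg A [generator_config()].
#' @param index Positive integer distinguishing images of the same class.
#' @return `H x W x 3` 8-bit array with attributes `label` (the class) and
#'   `fruit_box` (the analytic 0-based bounding box of the painted fruit,
#'   fields `x`, `y`, `w`, `h`).
#' @export
generate_plum_image <- function(cls, cfg = generator_config(), index = 1) {
  cls <- match.arg(cls, defect_classes())
  with_local_seed(derive_seed(cfg$seed, cls, index), {
    s <- cfg$image_size
    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    cx <- s / 2 + runif(1, -0.03, 0.03) * s
    cy <- s / 2 + runif(1, -0.03, 0.03) * s
    a <- runif(1, 0.30, 0.38) * s  # semi-axis x, in pixels
    b <- runif(1, 0.30, 0.38) * s  # semi-axis y
    r2 <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
    fruit <- r2 <= 1
    shade <- pmax(1 - 0.35 * r2, 0)
    base <- c(100, 160, 80) + runif(3, -10, 10)
    img <- array(cfg$background_level + rnorm(s * s * 3, 0, 1.5),
                 dim = c(s, s, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fruit] <- base[ch] * shade[fruit] + rnorm(sum(fruit), 0, 2)
      img[, , ch] <- plane
    }
    # defect alpha map in [0, 1] plus a defect colour
    alpha <- matrix(0, s, s)
    p <- cfg$class_params[[cls]]
    dcol <- c(0, 0, 0)
    place <- function(rho_max) {
      # random polar position well inside the fruit
      phi <- runif(1, 0, 2 * pi)
      rho <- runif(1, 0, rho_max)
      c(cx + rho * a * cos(phi), cy + rho * b * sin(phi))
    }
    if (cls == "rot") {
      dcol <- p$color
      frac <- runif(1, p$area_frac[1], p$area_frac[2])
      r0 <- sqrt(frac * a * b)
      ctr <- place(0.30)
      dx <- xs - ctr[1]; dy <- ys - ctr[2]
      phi <- atan2(dy, dx)
      wobble <- 1
      for (k in 2:5) {
        wobble <- wobble + 0.10 * sin(k * phi + runif(1, 0, 2 * pi))
      }
      alpha[sqrt(dx^2 + dy^2) <= r0 * wobble & fruit] <- 0.9
    } else if (cls == "scar") {
      dcol <- p$color
      n <- sample(p$n[1]:p$n[2], 1)
      for (i in seq_len(n)) {
        frac <- runif(1, p$area_frac[1], p$area_frac[2])
        r0 <- sqrt(frac * a * b)
        ctr <- place(0.45)
        nv <- sample(5:7, 1)
        vphi <- sort(runif(nv, 0, 2 * pi))
        vr <- r0 * runif(nv, 0.8, 1.25)
        # sharp-edged convex-ish polygon: point inside if radius below the
        # linear interpolation of vertex radii at its angle
        dx <- xs - ctr[1]; dy <- ys - ctr[2]
        phi <- atan2(dy, dx) %% (2 * pi)
        rthr <- approx(c(vphi, vphi[1] + 2 * pi), c(vr, vr[1]),
                       xout = pmax(pmin(phi, vphi[1] + 2 * pi), vphi[1]),
                       rule = 2)$y
        alpha[sqrt(dx^2 + dy^2) <= rthr & fruit] <- 0.9
      }
    } else if (cls == "crack") {
      dcol <- p$color
      len <- runif(1, p$length_frac[1], p$length_frac[2]) * a
      wdt <- sample(p$width[1]:p$width[2], 1)
      ctr <- place(0.25)
      theta <- runif(1, 0, 2 * pi)
      pos <- ctr
      nstep <- max(8, round(len / 2))
      for (i in seq_len(nstep)) {
        theta <- theta + rnorm(1, 0, 0.15)
        nxt <- pos + 2 * c(cos(theta), sin(theta))
        # stay inside 0.8 of the fruit radius
        if (((nxt[1] - cx) / a)^2 + ((nxt[2] - cy) / b)^2 > 0.64) {
          theta <- theta + pi / 2
          nxt <- pos + 2 * c(cos(theta), sin(theta))
        }
        pos <- nxt
        xi <- round(pos[1]); yi <- round(pos[2])
        rad <- wdt / 2
        xr <- max(1, floor(xi - rad)):min(s, ceiling(xi + rad))
        yr <- max(1, floor(yi - rad)):min(s, ceiling(yi + rad))
        for (xx in xr) for (yy in yr) {
          if ((xx - pos[1])^2 + (yy - pos[2])^2 <= rad^2 + 0.26 && fruit[yy, xx]) {
            alpha[yy, xx] <- 0.95
          }
        }
      }
    } else if (cls == "spot") {
      dcol <- p$color
      n <- sample(p$n[1]:p$n[2], 1)
      for (i in seq_len(n)) {
        ctr <- place(0.75)
        r0 <- runif(1, p$radius[1], p$radius[2])
        dx <- xs - ctr[1]; dy <- ys - ctr[2]
        alpha[dx^2 + dy^2 <= r0^2 & fruit] <- 0.85
      }
    }
    if (runif(1) < cfg$stem_probability) {
      # short brown stub at the fruit top
      x0 <- cx + runif(1, -0.1, 0.1) * a
      stem_len <- 0.12 * b
      for (t in seq(0, 1, length.out = 20)) {
        yy <- round(cy - b + t * stem_len)
        xx <- round(x0 + runif(1, -0.5, 0.5))
        if (yy >= 1 && yy <= s && xx >= 2 && xx <= s - 1) {
          for (ch in 1:3) img[yy, (xx - 1):(xx + 1), ch] <- c(75, 60, 35)[ch]
        }
      }
    }
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - alpha) + dcol[ch] * alpha
    }
    out <- clip8(img)
    attr(out, "label") <- cls
    # analytic 0-based box over pixel centres 1..s inside the ellipse
    attr(out, "fruit_box") <- list(
      x = ceiling(cx - a) - 1, y = ceiling(cy - b) - 1,
      w = floor(cx + a) - ceiling(cx - a) + 1,
      h = floor(cy + b) - ceiling(cy - b) + 1)
    out
  })
}

#' Generate a directory-per-class synthetic dataset
#'
#' @param cfg A [generator_config()].
#' @param counts Named integer vector of images per class (names from
#'   [defect_classes()]).
#' @param out_dir Output directory; one subdirectory per class is created.
#' @return Tibble manifest with columns `path`, `label`, `source_id`,
#'   written alongside the images as `manifest.csv`. Regeneration with the
#'   same seed is byte-identical.
#' @export
generate_plum_dataset <- function(cfg, counts, out_dir) {
  counts <- counts[intersect(defect_classes(), names(counts))]
  if (length(counts) == 0 || any(counts < 1)) {
    stop("counts must name at least one class with a positive count")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cls in names(counts)) {
    dir.create(file.path(out_dir, cls), showWarnings = FALSE)
    for (i in seq_len(counts[[cls]])) {
      id <- sprintf("%s_%04d", cls, i)
      rel <- file.path(cls, paste0(id, ".png"))
      write_image(generate_plum_image(cls, cfg, i),
                  file.path(out_dir, rel))
      rows[[length(rows) + 1]] <-
        tibble::tibble(path = rel, label = cls, source_id = id)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Pixel-statistics baseline classifier
#'
#' A deliberately simple reference labeller used to audit the generator's
#' class separability: it thresholds the dark-area fraction inside the
#' fruit, the number of dark components, the largest component's area and
#' its elongation. It is independent of the neural network.
#'
#' @param img A synthetic or real `H x W x 3` plum image.
#' @param background_level Background intensity used to find the fruit
#'   (default 18).
#' @return A single predicted class name.
#' @export
pixel_baseline_label <- function(img, background_level = 18) {
  assert_image(img)
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  fruit <- lum > background_level + 25
  if (sum(fruit) < 50) return("normal")
  # fill holes: very dark defects (cracks, deep rot) fall below the
  # brightness cut and would otherwise punch holes in the fruit mask
  holes <- .label_components(ifelse(fruit, 0L, 1L))
  border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                            holes[, 1], holes[, ncol(holes)]))
  fruit <- fruit | (holes > 0 & !(holes %in% border_labels))
  med <- stats::median(lum[fruit])
  dark <- fruit & lum < 0.7 * med
  f <- sum(dark) / sum(fruit)
  if (f < 0.004) return("normal")
  labels <- .label_components(ifelse(dark, 1L, 0L))
  sizes <- tabulate(labels[labels > 0])
  sizes <- sizes[sizes >= 3]
  if (length(sizes) == 0) return("normal")
  amax <- max(sizes) / sum(fruit)
  if (amax >= 0.075) return("rot")
  if (length(sizes) >= 8) return("spot")
  idx <- which(labels == which.max(tabulate(labels[labels > 0])), arr.ind = TRUE)
  wbox <- diff(range(idx[, 2])) + 1
  hbox <- diff(range(idx[, 1])) + 1
  fill <- max(sizes) / (wbox * hbox)
  aspect <- max(wbox, hbox) / min(wbox, hbox)
  if (aspect >= 3 || fill <= 0.30) return("crack")
  "scar"
}
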