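## Synthetic leaf-impression micrographs with exact ground truth.
##
## The generator emulates focus-stacked nail-polish impression imagery: a
## light, mottled epidermis background, elliptical stomata with a dark pore
## slit and a lighter guard-cell rim at random orientations, and
## negative-class artifacts (hair streaks, air bubbles, smudges). All
## randomness flows from one seed through R's Mersenne-Twister, so scenes
## are reproducible bit for bit.

#' Run code under a fixed, portable RNG state
#'
#' Evaluates `code` with the RNG seeded to `seed` using fixed generator kinds
#' (Mersenne-Twister / Inversion / Rejection), restoring the caller's RNG
#' state afterwards.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_fixed_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Configuration for the synthetic micrograph generator
#'
#' Defaults describe the imaging conditions the package targets: 1,600 x
#' 1,200 px micrographs whose stomata span 60-120 px along the major axis
#' (the size range the sliding-window detector handles best), well separated
#' (140 px) so a 120 px patch contains at most one full stoma, on a clean
#' high-contrast background. Contrast, noise and blur are exposed so harder
#' regimes can be generated.
#'
#' @param width_px,height_px Image size in pixels.
#' @param n_stomata Integer count, or a length-2 inclusive range from which
#'   a count is drawn per image.
#' @param stoma_major_axis_px Length-2 range of major-axis lengths (px).
#' @param aspect_ratio Length-2 range of minor/major axis ratios.
#' @param min_separation_px Minimum pairwise distance between stoma centers.
#' @param border_margin_px Minimum distance of a stoma center from the image
#'   border; default `major_axis/2 + 30` keeps every stoma fully visible and
#'   covered by several sliding windows.
#' @param artifact_rate Expected number of artifacts per image (Poisson).
#' @param noise_level Standard deviation of additive pixel noise.
#' @param blur_sigma_px Gaussian blur sigma in px (0 disables).
#' @param pore_contrast,rim_contrast Intensity depth of the dark pore slit
#'   and height of the light guard-cell rim.
#' @param background_level,texture_amplitude Mean background intensity and
#'   amplitude of the low-frequency mottling.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `"synth_config"` (a named list).
#' @export
synth_config <- function(width_px = 1600L, height_px = 1200L,
                         n_stomata = c(15L, 35L),
                         stoma_major_axis_px = c(60, 120),
                         aspect_ratio = c(0.4, 0.8),
                         min_separation_px = 140,
                         border_margin_px = NULL,
                         artifact_rate = 3,
                         noise_level = 0.02,
                         blur_sigma_px = 1,
                         pore_contrast = 0.35,
                         rim_contrast = 0.15,
                         background_level = 0.55,
                         texture_amplitude = 0.06,
                         seed = 1L) {
  cfg <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
              n_stomata = as.integer(n_stomata),
              stoma_major_axis_px = as.numeric(stoma_major_axis_px),
              aspect_ratio = as.numeric(aspect_ratio),
              min_separation_px = as.numeric(min_separation_px),
              border_margin_px = border_margin_px,
              artifact_rate = as.numeric(artifact_rate),
              noise_level = as.numeric(noise_level),
              blur_sigma_px = as.numeric(blur_sigma_px),
              pore_contrast = as.numeric(pore_contrast),
              rim_contrast = as.numeric(rim_contrast),
              background_level = as.numeric(background_level),
              texture_amplitude = as.numeric(texture_amplitude),
              seed = as.integer(seed))
  if (cfg$width_px <= 0 || cfg$height_px <= 0) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  if (length(cfg$n_stomata) == 1L) cfg$n_stomata <- rep(cfg$n_stomata, 2L)
  if (any(cfg$n_stomata < 0)) stop("n_stomata must be >= 0", call. = FALSE)
  ax <- cfg$stoma_major_axis_px
  if (length(ax) != 2L || any(ax <= 0) ||
      max(ax) >= min(cfg$width_px, cfg$height_px)) {
    stop("stoma_major_axis_px must be a positive range smaller than the image",
         call. = FALSE)
  }
  if (cfg$min_separation_px <= 0) stop("min_separation_px must be > 0", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

## Low-frequency mottled texture: bilinear interpolation of coarse Gaussian
## grids at two scales (value noise).
synth_background <- function(h, w, level, amplitude) {
  octave <- function(cell) {
    nr <- ceiling(h / cell) + 2L
    nc <- ceiling(w / cell) + 2L
    g <- matrix(stats::rnorm(nr * nc), nr, nc)
    yy <- (seq_len(h) - 1) / cell + 1
    xx <- (seq_len(w) - 1) / cell + 1
    y0 <- pmin(floor(yy), nr - 1L); fy <- yy - y0
    x0 <- pmin(floor(xx), nc - 1L); fx <- xx - x0
    Y0 <- rep(y0, times = w); X0 <- rep(x0, each = h)
    FY <- rep(fy, times = w); FX <- rep(fx, each = h)
    v <- g[cbind(Y0, X0)] * (1 - FY) * (1 - FX) +
      g[cbind(Y0 + 1L, X0)] * FY * (1 - FX) +
      g[cbind(Y0, X0 + 1L)] * (1 - FY) * FX +
      g[cbind(Y0 + 1L, X0 + 1L)] * FY * FX
    matrix(v, h, w)
  }
  level + amplitude * (0.75 * octave(max(8L, round(min(h, w) / 8))) +
                         0.35 * octave(max(4L, round(min(h, w) / 30))))
}

## Adds one stoma to `img` in place-style (returns modified matrix).
## Appearance model: soft light guard-cell rim around the ellipse boundary,
## dark elongated pore slit along the major axis, faint dark outline.
render_stoma <- function(img, x, y, major, aspect, theta,
                         pore_contrast, rim_contrast) {
  h <- nrow(img); w <- ncol(img)
  a <- major / 2
  b <- aspect * a
  R <- ceiling(a + 6)
  xs <- max(0L, floor(x - R)):min(w - 1L, ceiling(x + R))
  ys <- max(0L, floor(y - R)):min(h - 1L, ceiling(y + R))
  dx <- matrix(xs - x, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - y, length(ys), length(xs))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r <- sqrt((u / a)^2 + (v / b)^2)
  rim <- rim_contrast * exp(-((r - 0.78) / 0.16)^2)
  rp2 <- (u / (0.50 * a))^2 + (v / (0.22 * b))^2
  pore <- -pore_contrast * pmax(0, 1 - rp2)
  outline <- -0.25 * pore_contrast * exp(-((r - 1.04) / 0.07)^2)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + rim + pore + outline
  img
}

render_bubble <- function(img, x, y, rho) {
  h <- nrow(img); w <- ncol(img)
  R <- ceiling(rho * 1.3)
  xs <- max(0L, floor(x - R)):min(w - 1L, ceiling(x + R))
  ys <- max(0L, floor(y - R)):min(h - 1L, ceiling(y + R))
  dx <- matrix(xs - x, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - y, length(ys), length(xs))
  rr <- sqrt(dx^2 + dy^2) / rho
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
    0.10 * pmax(0, 1 - rr^2) - 0.30 * exp(-((rr - 1) / 0.05)^2)
  img
}

render_smudge <- function(img, x, y, rho, amp) {
  h <- nrow(img); w <- ncol(img)
  R <- ceiling(rho * 2)
  xs <- max(0L, floor(x - R)):min(w - 1L, ceiling(x + R))
  ys <- max(0L, floor(y - R)):min(h - 1L, ceiling(y + R))
  dx <- matrix(xs - x, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - y, length(ys), length(xs))
  rr2 <- (dx^2 + dy^2) / rho^2
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amp * exp(-rr2)
  img
}

## Stamps a dark, slightly curved hair streak; returns list(img, path) or
## NULL when the path cannot avoid the stomata.
render_hair <- function(img, stoma_xy, stoma_clear) {
  h <- nrow(img); w <- ncol(img)
  for (try in seq_len(40L)) {
    x0 <- stats::runif(1, 0, w - 1)
    y0 <- stats::runif(1, 0, h - 1)
    phi <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.15, 0.4) * min(w, h)
    curv <- stats::runif(1, -1.5, 1.5) / len
    t <- seq(0, len, by = 1.5)
    ang <- phi + curv * t
    px <- x0 + cumsum(c(0, diff(t)) * cos(ang))
    py <- y0 + cumsum(c(0, diff(t)) * sin(ang))
    keep <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    px <- px[keep]; py <- py[keep]
    if (length(px) < 10L) next
    if (nrow(stoma_xy)) {
      d2 <- outer(px, stoma_xy[, 1L], "-")^2 + outer(py, stoma_xy[, 2L], "-")^2
      if (min(d2) < min(stoma_clear)^2) next
    }
    for (k in seq_along(px)) {
      cx <- round(px[k]); cy <- round(py[k])
      xs <- max(0L, cx - 2L):min(w - 1L, cx + 2L)
      ys <- max(0L, cy - 2L):min(h - 1L, cy + 2L)
      dd <- outer((ys - py[k])^2, (xs - px[k])^2, "+")
      img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] - 0.22 * exp(-dd / 2.5)
    }
    return(list(img = img, x = mean(px), y = mean(py)))
  }
  NULL
}

#' Generate one synthetic micrograph with exact annotations
#'
#' Renders a seeded synthetic leaf-impression micrograph: mottled epidermis
#' background, `n_stomata` oriented elliptical stomata placed by rejection
#' sampling under the minimum-separation and border-margin constraints,
#' Poisson-distributed artifacts that never overlap stomata, additive pixel
#' noise and an optional Gaussian blur. Every drawn stoma yields exactly one
#' annotation at its ellipse center.
#'
#' @param cfg A [synth_config()].
#' @param image_id Identifier for the scene.
#' @return An object of class `"synth_scene"`: a list with `micrograph`
#'   ([micrograph()]), `annotations` ([stoma_annotations()]), `artifacts`
#'   (data.frame `x`, `y`, `kind`) and `config`.
#' @examples
#' sc <- generate_micrograph(synth_config(width_px = 400L, height_px = 300L,
#'                                        n_stomata = 3L, seed = 7L))
#' nrow(sc$annotations)
#' @export
generate_micrograph <- function(cfg, image_id = "sim_001") {
  stopifnot(inherits(cfg, "synth_config"))
  with_fixed_seed(cfg$seed, {
    w <- cfg$width_px; h <- cfg$height_px
    n <- if (cfg$n_stomata[1L] == cfg$n_stomata[2L]) cfg$n_stomata[1L] else
      sample(cfg$n_stomata[1L]:cfg$n_stomata[2L], 1L)

    ## --- place stomata (rejection sampling) ---
    major <- stats::runif(n, cfg$stoma_major_axis_px[1L], cfg$stoma_major_axis_px[2L])
    aspect <- stats::runif(n, cfg$aspect_ratio[1L], cfg$aspect_ratio[2L])
    theta <- stats::runif(n, 0, pi)
    margin <- if (is.null(cfg$border_margin_px)) major / 2 + 30 else
      rep_len(cfg$border_margin_px, n)
    xs <- numeric(0); ys <- numeric(0)
    max_tries <- 300L * max(n, 1L)
    tries <- 0L
    for (i in seq_len(n)) {
      if (margin[i] * 2 >= w || margin[i] * 2 >= h) {
        stop(sprintf(
          "packing error: image %d x %d px too small for border margin %.0f px (placed %d of %d stomata)",
          w, h, margin[i], length(xs), n), call. = FALSE)
      }
      placed <- FALSE
      while (tries < max_tries) {
        tries <- tries + 1L
        cx <- stats::runif(1, margin[i], w - margin[i])
        cy <- stats::runif(1, margin[i], h - margin[i])
        if (!length(xs) ||
            min((xs - cx)^2 + (ys - cy)^2) >= cfg$min_separation_px^2) {
          xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop(sprintf(
          "packing error: could only place %d of %d stomata at min_separation %.0f px in a %d x %d px image",
          length(xs), n, cfg$min_separation_px, w, h), call. = FALSE)
      }
    }

    ## --- render ---
    img <- synth_background(h, w, cfg$background_level, cfg$texture_amplitude)
    for (i in seq_len(n)) {
      img <- render_stoma(img, xs[i], ys[i], major[i], aspect[i], theta[i],
                          cfg$pore_contrast, cfg$rim_contrast)
    }

    ## --- artifacts (never overlapping stomata) ---
    arts <- data.frame(x = numeric(0), y = numeric(0), kind = character(0),
                       stringsAsFactors = FALSE)
    n_art <- stats::rpois(1, cfg$artifact_rate)
    stoma_xy <- cbind(xs, ys)
    clear <- if (n) major / 2 + 15 else numeric(0)
    for (j in seq_len(n_art)) {
      kind <- sample(c("hair", "bubble", "smudge"), 1L)
      if (kind == "hair") {
        res <- render_hair(img, stoma_xy, if (n) clear else 1)
        if (!is.null(res)) {
          img <- res$img
          arts <- rbind(arts, data.frame(x = res$x, y = res$y, kind = "hair",
                                         stringsAsFactors = FALSE))
        }
      } else {
        rho <- if (kind == "bubble") stats::runif(1, 25, 60) else
          stats::runif(1, 30, 80)
        ok <- FALSE
        for (try in seq_len(40L)) {
          ax <- stats::runif(1, 0, w - 1); ay <- stats::runif(1, 0, h - 1)
          if (!n || min(sqrt((xs - ax)^2 + (ys - ay)^2) - clear) >= rho + 5) {
            ok <- TRUE; break
          }
        }
        if (!ok) next
        img <- if (kind == "bubble") render_bubble(img, ax, ay, rho) else
          render_smudge(img, ax, ay, rho, stats::runif(1, -0.12, 0.12))
        arts <- rbind(arts, data.frame(x = ax, y = ay, kind = kind,
                                       stringsAsFactors = FALSE))
      }
    }

    ## --- noise, blur, 8-bit quantization ---
    if (cfg$noise_level > 0) {
      img <- img + stats::rnorm(length(img), sd = cfg$noise_level)
    }
    if (cfg$blur_sigma_px > 0) {
      img <- EBImage::gblur(img, sigma = cfg$blur_sigma_px)
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255

    anns <- stoma_annotations(image_id = image_id, x_px = xs, y_px = ys,
                              length_px = major, width_px = w, height_px = h)
    structure(list(micrograph = micrograph(img, image_id = image_id),
                   annotations = anns, artifacts = arts, config = cfg),
              class = "synth_scene")
  })
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf("synth_scene '%s': %d x %d px, %d stomata, %d artifacts\n",
              x$micrograph$image_id, micrograph_width(x$micrograph),
              micrograph_height(x$micrograph), nrow(x$annotations),
              nrow(x$artifacts)))
  invisible(x)
}

#' Generate a dataset of synthetic micrographs on disk
#'
#' Writes `n_images` seeded scenes as 8-bit grayscale PNGs plus one combined
#' annotation CSV (`image_id,x_px,y_px,length_px`). Per-image seeds are
#' derived deterministically from the master seed, so the same call always
#' produces identical files.
#'
#' @param n_images Number of images (>= 1).
#' @param cfg A [synth_config()]; its `seed` is the master seed.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the list of `synth_scene` objects, with attributes
#'   `image_paths` and `annotation_path`.
#' @export
generate_dataset <- function(n_images, cfg, out_dir, prefix = "sim") {
  stopifnot(inherits(cfg, "synth_config"), n_images >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  scenes <- vector("list", n_images)
  paths <- character(n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((as.double(cfg$seed) * 10007 + i) %% 2147483647)
    id <- sprintf("%s_%03d", prefix, i)
    scenes[[i]] <- generate_micrograph(cfg_i, image_id = id)
    paths[i] <- file.path(out_dir, paste0(id, ".png"))
    png::writePNG(scenes[[i]]$micrograph$pixels, paths[i])
  }
  anns <- do.call(rbind, lapply(scenes, function(s) as.data.frame(s$annotations)))
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(anns, ann_path)
  attr(scenes, "image_paths") <- paths
  attr(scenes, "annotation_path") <- ann_path
  invisible(scenes)
}
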