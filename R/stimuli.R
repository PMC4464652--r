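#' @useDynLib vosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm rnorm runif sd pt
#' @importFrom utils write.csv write.table tail
NULL

# Canvas geometry. Images are 70 rows x 60 columns; flattened row-major
# (index = row * 60 + col, 0-based) so a column of the stimulus matrices is
# one face.
CANVAS_ROWS <- 70L
CANVAS_COLS <- 60L
N_PIXELS <- CANVAS_ROWS * CANVAS_COLS

# Disjoint feature regions (1-based row ranges, full width).
FEATURE_REGIONS <- list(
  eye  = c(11L, 29L),
  nose = c(31L, 47L),
  lip  = c(49L, 63L)
)

# Verbal layer unit order; one localist unit per label, paired per feature.
VERBAL_UNITS <- c("drooping", "slanted", "long", "button", "thick", "downturned")

## ---- low-level raster helpers -------------------------------------------

blank_canvas <- function() matrix(FALSE, CANVAS_ROWS, CANVAS_COLS)

canvas_grid <- local({
  r <- matrix(seq_len(CANVAS_ROWS), CANVAS_ROWS, CANVAS_COLS)
  c <- matrix(rep(seq_len(CANVAS_COLS), each = CANVAS_ROWS), CANVAS_ROWS, CANVAS_COLS)
  list(r = r, c = c)
})

px_disc <- function(r0, c0, radius) {
  (canvas_grid$r - r0)^2 + (canvas_grid$c - c0)^2 <= radius^2
}

px_rect <- function(r1, r2, c1, c2) {
  canvas_grid$r >= r1 & canvas_grid$r <= r2 & canvas_grid$c >= c1 & canvas_grid$c <= c2
}

# Thick line segment: pixels within half_width of the segment (r0,c0)-(r1,c1).
px_stroke <- function(r0, c0, r1, c1, half_width = 1.2) {
  dr <- r1 - r0; dc <- c1 - c0
  len2 <- dr^2 + dc^2
  t <- ((canvas_grid$r - r0) * dr + (canvas_grid$c - c0) * dc) / len2
  t <- pmin(pmax(t, 0), 1)
  pr <- r0 + t * dr; pc <- c0 + t * dc
  (canvas_grid$r - pr)^2 + (canvas_grid$c - pc)^2 <= half_width^2
}

# Downward-opening parabolic band: r = apex_r + (c - c0)^2 / k.
px_arc <- function(apex_r, c0, k, half_span, half_width = 1.2) {
  rc <- apex_r + (canvas_grid$c - c0)^2 / k
  abs(canvas_grid$r - rc) <= half_width & abs(canvas_grid$c - c0) <= half_span
}

## ---- glyph bank ----------------------------------------------------------

# Paired angled strokes. Same-label variants share the stroke core but
# differ in length and thickness, so each variant also has pixels of its
# own (big = long and thin, small = short and thick); nesting one variant
# inside the other would make them indistinguishable for reconstruction.
eye_glyph <- function(slope, half_len, half_width) {
  g <- blank_canvas()
  for (cc in c(16, 45)) {
    out_dir <- if (cc < 30) -1 else 1  # outward = toward the nearer canvas edge
    g <- g | px_stroke(20 + slope * half_len, cc + out_dir * half_len,
                       20 - slope * half_len, cc - out_dir * half_len,
                       half_width)
  }
  g
}

nose_long <- function(r1, r2, c1, c2) px_rect(r1, r2, c1, c2)
nose_button <- function(r0, radius) px_disc(r0, 30, radius)

lip_thick <- function(top_row) px_rect(top_row, top_row + 5, 18, 42)
lip_downturned <- function(parallel) {
  if (parallel) {
    px_arc(51.5, 30, 36, 9, 1.3) | px_arc(55, 30, 36, 9, 1.3)
  } else {
    px_arc(51, 30, 36, 13, 1.6)
  }
}

#' Parametric glyph bank for the synthetic face stimuli
#'
#' Builds the 12 binary feature glyphs (4 subordinate types for each of eyes,
#' nose and lips) on the 70 x 60 canvas. Within each feature, subordinate
#' types 0-1 share the first verbal label and types 2-3 the second; the two
#' subordinate types under one label are size/position variants of the same
#' shape, so faces sharing a verbal label share most pixels of that feature
#' region while faces with the opposite label share few. Eyes are paired
#' angled strokes (drooping = outer corners low, slanted = outer corners
#' high; big/small variants). Noses are a vertical bar (long; tall/short) or
#' a disc (button; big/small). Lips are a filled band (thick; bottom/top
#' position) or a downward arc (downturned; single/parallel double arc).
#'
#' @return An object of class `glyph_bank`: a list with elements `eye`,
#'   `nose`, `lip`, each a list of 4 logical 70 x 60 matrices (subordinate
#'   types 0-3), plus a `version` string.
#' @export
glyph_bank <- function() {
  bank <- list(
    eye = list(
      eye_glyph(0.55, 9, 1.2),   # type 0: big drooping (long, thin)
      eye_glyph(0.55, 5.5, 2.1), # type 1: small drooping (short, thick)
      eye_glyph(-0.55, 9, 1.2),  # type 2: big slanted
      eye_glyph(-0.55, 5.5, 2.1) # type 3: small slanted
    ),
    nose = list(
      nose_long(32, 46, 29, 31),   # type 0: big (tall) long nose
      nose_long(35, 43, 27, 33),   # type 1: small (short, wide) long nose
      nose_button(40, 6),          # type 2: big button nose
      nose_button(36, 4)           # type 3: small button nose (higher)
    ),
    lip = list(
      lip_thick(53),        # type 0: bottom thick lip
      lip_thick(51),        # type 1: top thick lip
      lip_downturned(FALSE),# type 2: normal downturned lip (single wide arc)
      lip_downturned(TRUE)  # type 3: parallel downturned lip (double arc)
    ),
    version = "vosim-glyphs-2"
  )
  class(bank) <- "glyph_bank"
  bank
}

## ---- face specs ----------------------------------------------------------

#' Enumerate the 64 factorial face specifications
#'
#' Crosses 4 eye x 4 nose x 4 lip subordinate types into 64 unique faces.
#' Each feature's verbal label is the subordinate type integer-divided by 2,
#' so every verbal label triple is shared by exactly 8 faces (2 x 2 x 2
#' subordinate combinations).
#'
#' @return A data.frame with 64 rows: `item_id` (1-64), `eye_type`,
#'   `nose_type`, `lip_type` (0-3), and derived `eye_label`, `nose_label`,
#'   `lip_label` (0-1).
#' @export
enumerate_face_specs <- function() {
  grid <- expand.grid(lip_type = 0:3, nose_type = 0:3, eye_type = 0:3)
  specs <- data.frame(
    item_id = seq_len(64),
    eye_type = grid$eye_type,
    nose_type = grid$nose_type,
    lip_type = grid$lip_type
  )
  specs$eye_label <- specs$eye_type %/% 2L
  specs$nose_label <- specs$nose_type %/% 2L
  specs$lip_label <- specs$lip_type %/% 2L
  specs
}

#' Render one face as a binary image
#'
#' Places the three feature glyphs of a face spec on a white 70 x 60 canvas
#' (black pixel = 1). Glyphs live in fixed disjoint row bands (eyes 11-29,
#' nose 31-47, lips 49-63); a glyph bank whose glyphs leak outside their
#' band is rejected.
#'
#' @param spec One row of [enumerate_face_specs()].
#' @param glyphs A [glyph_bank()].
#' @return A 4200-long 0/1 vector, row-major flattened (index = row*60+col,
#'   0-based).
#' @export
render_face_image <- function(spec, glyphs = glyph_bank()) {
  stopifnot(inherits(glyphs, "glyph_bank"))
  parts <- list(
    eye  = glyphs$eye[[spec$eye_type + 1L]],
    nose = glyphs$nose[[spec$nose_type + 1L]],
    lip  = glyphs$lip[[spec$lip_type + 1L]]
  )
  img <- blank_canvas()
  for (feat in names(parts)) {
    g <- parts[[feat]]
    region <- FEATURE_REGIONS[[feat]]
    rows_on <- which(apply(g, 1, any))
    if (length(rows_on) && (min(rows_on) < region[1] || max(rows_on) > region[2])) {
      stop("glyph for feature '", feat, "' leaks outside its region (rows ",
           region[1], "-", region[2], ")")
    }
    img <- img | g
  }
  flatten_image(img)
}

# Row-major flatten of a canvas matrix to a numeric vector.
flatten_image <- function(m) as.numeric(t(m))

# Inverse of flatten_image.
unflatten_image <- function(v) matrix(v, CANVAS_ROWS, CANVAS_COLS, byrow = TRUE)

## ---- retinotopic smoothing ----------------------------------------------

# 1-D normalized Gaussian kernel; radius at least 1 so sd -> 0 degenerates
# to the identity kernel.
gaussian_kernel <- function(sd) {
  if (sd <= 0) return(1)
  radius <- max(1L, ceiling(4 * sd))
  k <- dnorm(seq(-radius, radius), sd = sd)
  k / sum(k)
}

# Separable 2-D convolution with reflect padding along one dimension.
conv1d_reflect <- function(x, k) {
  n <- length(x)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x * k)
  idx <- c(r:1, seq_len(n), n:(n - r + 1L))
  padded <- x[idx]
  as.numeric(stats::filter(padded, k, sides = 2)[(r + 1L):(r + n)])
}

#' Degrade a binary face image into its retinotopic input
#'
#' Smooths the image by separable 2-D Gaussian convolution with a normalized
#' kernel (reflect-padded borders) and clips to `[0, 1]`. With `sd = 0` the
#' image is returned unchanged; a constant image is preserved exactly.
#'
#' @param image A 4200-long 0/1 vector from [render_face_image()].
#' @param sd Gaussian kernel standard deviation in pixels (default 0.2).
#' @return A 4200-long vector in `[0, 1]`, same flattening as the input.
#' @export
make_retinotopic_input <- function(image, sd = 0.2) {
  stopifnot(sd >= 0, length(image) == N_PIXELS)
  if (sd == 0) return(as.numeric(image))
  k <- gaussian_kernel(sd)
  m <- unflatten_image(as.numeric(image))
  m <- t(apply(m, 1, conv1d_reflect, k = k))
  m <- apply(m, 2, conv1d_reflect, k = k)
  flatten_image(pmin(pmax(m, 0), 1))
}

## ---- stimulus set --------------------------------------------------------

# 6-unit localist verbal vector for one spec.
verbal_vector <- function(spec) {
  v <- numeric(6)
  v[1L + spec$eye_label] <- 1
  v[3L + spec$nose_label] <- 1
  v[5L + spec$lip_label] <- 1
  v
}

#' Build the full 64-face stimulus set
#'
#' Assembles, for each of the 64 factorial faces, the binary target image,
#' the Gaussian-degraded retinotopic input and the 6-bit localist verbal
#' vector, and samples (with the given seed) the random 32/32 split into
#' trained ("old") and untrained ("new") faces. Regeneration with the same
#' seed and glyph bank is bit-identical.
#'
#' @param seed Integer seed controlling the trained/untrained split.
#' @param sd Gaussian smoothing width in pixels for the retinotopic input.
#' @param glyphs A [glyph_bank()].
#' @return An object of class `stimulus_set`: list with `specs` (64-row
#'   data.frame including a logical `trained` column), `images`, `retinotopic`
#'   (4200 x 64 matrices, one face per column), `verbal` (6 x 64), and the
#'   generation parameters `seed`, `sd`, `glyph_version`.
#' @export
build_stimulus_set <- function(seed = 1L, sd = 0.2, glyphs = glyph_bank()) {
  specs <- enumerate_face_specs()
  images <- vapply(seq_len(64),
                   function(i) render_face_image(specs[i, ], glyphs),
                   numeric(N_PIXELS))
  retino <- apply(images, 2, make_retinotopic_input, sd = sd)
  verbal <- vapply(seq_len(64), function(i) verbal_vector(specs[i, ]), numeric(6))
  rownames(verbal) <- VERBAL_UNITS
  set.seed(seed)
  trained <- rep(FALSE, 64)
  trained[sample.int(64, 32)] <- TRUE
  specs$trained <- trained
  structure(
    list(specs = specs, images = images, retinotopic = retino, verbal = verbal,
         seed = as.integer(seed), sd = sd, glyph_version = glyphs$version),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set: 64 faces (4 eye x 4 nose x 4 lip subordinate types)\n")
  cat(sprintf("  canvas %d x %d, smoothing sd = %g px, glyphs %s, seed %d\n",
              CANVAS_ROWS, CANVAS_COLS, x$sd, x$glyph_version, x$seed))
  cat(sprintf("  trained ('old') faces: %d, untrained ('new'): %d\n",
              sum(x$specs$trained), sum(!x$specs$trained)))
  invisible(x)
}

#' Item ids of trained ("old") or untrained ("new") faces
#' @param stimuli A `stimulus_set`.
#' @param trained Logical; `TRUE` for the trained half.
#' @return Integer vector of 32 item ids.
#' @export
item_ids <- function(stimuli, trained = TRUE) {
  stimuli$specs$item_id[stimuli$specs$trained == trained]
}

#' Export a stimulus set as plain-text files
#'
#' Writes the binary images as PGM (P2, one file per face), the layer vectors
#' as CSV (one row per item) and a JSON-like manifest recording the seed,
#' glyph-bank version, smoothing width and the row-major 0-based flattening
#' convention.
#'
#' @param stimuli A `stimulus_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_stimulus_set <- function(stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(64)) {
    m <- unflatten_image(stimuli$images[, i])
    con <- file(file.path(dir, sprintf("face_%02d.pgm", i)), "w")
    writeLines(c("P2", paste(CANVAS_COLS, CANVAS_ROWS), "1"), con)
    write.table(1 - m, con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  write.csv(cbind(item = seq_len(64), t(stimuli$retinotopic)),
            file.path(dir, "retinotopic.csv"), row.names = FALSE)
  write.csv(cbind(item = seq_len(64), t(stimuli$verbal)),
            file.path(dir, "verbal.csv"), row.names = FALSE)
  write.csv(stimuli$specs, file.path(dir, "specs.csv"), row.names = FALSE)
  manifest <- sprintf(
    paste0('{"seed": %d, "sd": %g, "glyphs": "%s", ',
           '"flattening": "row-major, index = row*%d + col, 0-based", ',
           '"pixel_coding": "1 = black"}'),
    stimuli$seed, stimuli$sd, stimuli$glyph_version, CANVAS_COLS)
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
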