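test_that("factorial face specs enumerate the full 4x4x4 design", {
  specs <- enumerate_face_specs()
  expect_equal(nrow(specs), 64L)
  expect_equal(specs$item_id, 1:64)
  expect_false(any(duplicated(specs[, c("eye_type", "nose_type", "lip_type")])))
  # verbal label deterministic in subordinate type
  expect_equal(specs$eye_label, specs$eye_type %/% 2L)
  # every verbal label triple is shared by exactly 8 faces
  triple <- paste(specs$eye_label, specs$nose_label, specs$lip_label)
  expect_true(all(table(triple) == 8L))
  # faces differing only in the subordinate type within a label share labels
  same_label <- specs[specs$eye_type %in% 0:1 & specs$nose_type == 0 &
                        specs$lip_type == 0, ]
  expect_equal(length(unique(same_label$eye_label)), 1L)
})

test_that("rendered faces are 4200-pixel binary images, pairwise distinct, with
           deterministic feature regions", {
  st <- std_stimuli()
  expect_equal(dim(st$images), c(4200L, 64L))
  expect_true(all(st$images %in% c(0, 1)))
  expect_equal(length(unique(apply(st$images, 2, paste, collapse = ""))), 64L)
  # same eye subordinate type -> identical pixels in the eye region
  eyes <- region_idx(11:29)
  same_eye <- which(st$specs$eye_type == 2)
  for (j in same_eye[-1]) {
    expect_identical(st$images[eyes, same_eye[1]], st$images[eyes, j])
  }
  # feature regions are disjoint: nose rows hold no eye/lip pixels etc.
  outside <- setdiff(seq_len(4200), region_idx(c(11:29, 31:47, 49:63)))
  expect_true(all(st$images[outside, ] == 0))
})

test_that("a glyph leaking outside its region is rejected", {
  bad <- glyph_bank()
  bad$eye[[1]][40, 30] <- TRUE  # row 40 is in the nose band
  expect_error(render_face_image(enumerate_face_specs()[1, ], bad), "leak")
})

test_that("retinotopic smoothing is a normalized clipped convolution", {
  img <- std_stimuli()$images[, 1]
  expect_equal(make_retinotopic_input(img, 0), img)
  expect_equal(make_retinotopic_input(rep(0, 4200), 1.3), rep(0, 4200))
  # normalized kernel preserves a constant image exactly
  expect_equal(make_retinotopic_input(rep(1, 4200), 2.1), rep(1, 4200),
               tolerance = 1e-12)
  rt <- make_retinotopic_input(img, 0.8)
  expect_true(all(rt >= 0 & rt <= 1))
  expect_gt(sum(rt > 0 & rt < 1), 0)  # smoothing produced graded values
})

test_that("stimulus set regenerates bit-identically with a 32/32 split and
           3-hot verbal vectors", {
  s1 <- build_stimulus_set(seed = 11)
  s2 <- build_stimulus_set(seed = 11)
  expect_identical(s1, s2)
  expect_equal(sum(s1$specs$trained), 32L)
  expect_equal(sum(!s1$specs$trained), 32L)
  expect_true(all(colSums(s1$verbal) == 3))
  pair_sums <- s1$verbal[c(1, 3, 5), ] + s1$verbal[c(2, 4, 6), ]
  expect_true(all(pair_sums == 1))
  s3 <- build_stimulus_set(seed = 12)
  expect_false(identical(s1$specs$trained, s3$specs$trained))
})

test_that("faces sharing a verbal triple overlap more than faces sharing no
           label", {
  st <- std_stimuli()
  specs <- st$specs
  pairs <- combn(64, 2)
  shared <- apply(pairs, 2, function(p) {
    sum(specs[p[1], c("eye_label", "nose_label", "lip_label")] ==
          specs[p[2], c("eye_label", "nose_label", "lip_label")])
  })
  overlap <- apply(pairs, 2, function(p) {
    sum(st$images[, p[1]] == 1 & st$images[, p[2]] == 1)
  })
  expect_gt(mean(overlap[shared == 3]), mean(overlap[shared == 0]))
  # similarity grows monotonically with the number of shared labels
  means <- tapply(overlap, shared, mean)
  expect_true(all(diff(means) > 0))
})

test_that("stimulus export writes plain-text artifacts", {
  dir <- withr::local_tempdir()
  write_stimulus_set(std_stimuli(), dir)
  expect_true(file.exists(file.path(dir, "face_01.pgm")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  specs <- read.csv(file.path(dir, "specs.csv"))
  expect_equal(nrow(specs), 64L)
  pgm <- readLines(file.path(dir, "face_01.pgm"), n = 3)
  expect_equal(pgm[1], "P2")
  expect_equal(pgm[2], "60 70")
})
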