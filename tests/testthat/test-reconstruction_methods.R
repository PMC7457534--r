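# small shared fixture: a coarse plant and its per-camera partials
plant_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- plant_spec(resolution = 5)
      pl <- generate_plant(sp)
      rig <- camera_rig(center = c(0, 0, pl$ground_truth$plant_height / 2))
      sch <- turntable_schedule()
      nm <- noise_model(seed = 1)
      partials <- lapply(2:6, function(cam)
        reconstruct_single_vza(pl$mesh, rig, cam, sch, nm))
      cache <<- list(plant = pl, rig = rig, sch = sch, nm = nm,
                     partials = partials)
    }
    cache
  }
})

test_that("merging complementary halves restores full coverage", {
  lf <- generate_leaf(40, 24, attach = c(-20, 0, 30), resolution = 3)
  nfc <- n_faces(lf$mesh)
  nv <- n_vertices(lf$mesh)
  half1 <- seq_len(floor(nfc / 2))
  half2 <- setdiff(seq_len(nfc), half1)
  fake_partial <- function(faces, camera) {
    sigma <- rep(NA_real_, nv)
    sigma[unique(as.vector(lf$mesh$faces[faces, , drop = FALSE]))] <- 0.1
    structure(list(camera = camera, vza = 36, faces = sort(faces),
                   vertices = lf$mesh$vertices, sigma = sigma,
                   scene_faces = lf$mesh$faces,
                   scene_labels = lf$mesh$labels,
                   visible = matrix(TRUE, nfc, 1)),
              class = c("partial_model"))
  }
  m <- merge_method1(list(fake_partial(half1, "C3"), fake_partial(half2, "C4")))
  expect_equal(m$faces, seq_len(nfc))
  ref <- c(L1 = sum(face_areas(lf$mesh)))
  expect_equal(unname(completeness(m, ref)), 100)
})

test_that("merge is idempotent and fuses noise scales as inverse variance", {
  fx <- plant_fixture()
  p <- fx$partials[[3]]
  m <- merge_method1(list(p, p))
  expect_identical(m$faces, sort(unique(p$faces)))
  expect_equal(m$vertices, p$vertices)
  det <- !is.na(p$sigma)
  expect_equal(m$sigma[det], p$sigma[det], tolerance = 1e-9)

  # two distinct cameras with equal sigma: fused sigma = s / sqrt(2)
  p2 <- p
  p2$camera <- "C99"
  m2 <- merge_method1(list(p, p2))
  expect_equal(m2$sigma[det], p$sigma[det] / sqrt(2), tolerance = 1e-9)

  # mismatched scenes are rejected
  other <- plant_fixture()$partials[[1]]
  other$scene_faces <- other$scene_faces[-1, , drop = FALSE]
  expect_error(merge_method1(list(p, other)), "different scenes")
})

test_that("Method 2 detects a subset of Method 1 and inherits its fusion", {
  fx <- plant_fixture()
  m1 <- merge_method1(fx$partials)
  m2 <- joint_model_method2(fx$plant$mesh, fx$rig, 2:6, fx$sch, fx$nm,
                            partials = fx$partials)
  expect_true(all(m2$faces %in% m1$faces))
  expect_identical(m2$method, "M2")
  # faces seen by a single camera only are exactly the ones dropped
  nsee <- rowSums(vapply(fx$partials, function(p) rowSums(p$visible) > 0,
                         logical(nrow(m1$scene_faces))))
  dropped <- setdiff(m1$faces, m2$faces)
  expect_true(all(nsee[dropped] < 2))
  expect_error(joint_model_method2(fx$plant$mesh, fx$rig, 3, fx$sch, fx$nm),
               "at least 2")
})

test_that("adding a camera never lowers per-organ completeness", {
  fx <- plant_fixture()
  leaves <- fx$plant$ground_truth$organs
  leaves <- leaves[leaves$type == "leaf", ]
  ref <- setNames(leaves$area_cm2 * 100, leaves$organ)
  prev <- rep(0, length(ref))
  for (k in seq_along(fx$partials)) {
    cc <- completeness(merge_method1(fx$partials[seq_len(k)]), ref)
    expect_true(all(cc >= prev - 1e-9))
    prev <- cc
  }
  # the merge is at least as complete as any single input
  singles <- vapply(fx$partials, function(p) completeness(p, ref), ref)
  expect_true(all(prev >= apply(singles, 1, max) - 1e-9))
})

test_that("completeness reports the detected share of the reference area", {
  lf <- generate_leaf(40, 24, resolution = 3)
  ref <- c(L1 = sum(face_areas(lf$mesh)))
  full <- structure(list(camera = "C4", vza = 36,
                         faces = seq_len(n_faces(lf$mesh)),
                         vertices = lf$mesh$vertices,
                         sigma = rep(0.1, n_vertices(lf$mesh)),
                         scene_faces = lf$mesh$faces,
                         scene_labels = lf$mesh$labels),
                    class = "partial_model")
  expect_equal(unname(completeness(full, ref)), 100)
  expect_error(completeness(full, c(Lx = 10)), "unknown organ")
  # half the faces detected (by area) reports the matching share
  half <- full
  ar <- face_areas(lf$mesh)
  o <- order(ar)
  half$faces <- o[cumsum(ar[o]) <= sum(ar) / 2]
  share <- sum(ar[half$faces]) / sum(ar) * 100
  expect_equal(unname(completeness(half, ref)), round(share, 1),
               tolerance = 0.05)
})

test_that("the end-to-end comparison behaves like the two-strategy study", {
  fx <- plant_fixture()
  cmp <- compare_methods(fx$plant$mesh, fx$plant$ground_truth, fx$rig, 2:6,
                         fx$sch, fx$nm)
  expect_true(all(cmp$m2$faces %in% cmp$m1$faces))
  expect_gte(cmp$ng[["M2"]], cmp$ng[["M1"]])
  d <- as.data.frame(cmp)
  expect_true(all(c("organ", "trait", "direct", "m1_estimate",
                    "m2_estimate", "m1_ng", "m2_ng") %in% names(d)))
  # with the study noise level every leaf trait lands within a few percent
  leaf_err <- d$m1_error_pct[d$trait %in% c("area", "length", "width") &
                               !d$m1_ng]
  expect_lt(max(leaf_err), 10)
})

test_that("the noise-free full-visibility limit reproduces ground truth", {
  fx <- plant_fixture()
  pl <- fx$plant
  # a fully detected, unperturbed "reconstruction"
  full <- structure(list(camera = "C4", vza = 36,
                         faces = seq_len(n_faces(pl$mesh)),
                         vertices = pl$mesh$vertices,
                         sigma = rep(1e-6, n_vertices(pl$mesh)),
                         scene_faces = pl$mesh$faces,
                         scene_labels = pl$mesh$labels,
                         visible = matrix(TRUE, n_faces(pl$mesh), 1)),
                    class = "partial_model")
  m <- merge_method1(list(full))
  tr <- extract_traits(m, pl$ground_truth)
  et <- build_error_table(tr, pl$ground_truth)
  expect_lt(max(et$entries$error_pct, na.rm = TRUE), 0.01)
})
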