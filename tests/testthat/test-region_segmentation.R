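test_that("cumulative area curve handles simple and analytic cases", {
  # all-horizontal mesh: one step holding the full area at 0 degrees
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                      rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  cv <- cumulative_area_curve(sq)
  expect_equal(unique(round(cv$angle, 9)), 0)
  expect_equal(cv$total, 100)

  # two faces at 30 and 60 degrees with areas 1 and 2
  t30 <- rigid_transform(
    triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(30))
  t60 <- rigid_transform(
    triangle_mesh(rbind(c(5, 0, 0), c(7, 0, 0), c(5, 2, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(60))
  cv2 <- cumulative_area_curve(phenomesh:::merge_meshes(list(t30, t60)))
  expect_equal(cv2$angle, c(30, 60), tolerance = 1e-9)
  expect_equal(cv2$area, c(1, 3), tolerance = 1e-12)

  # unit hemisphere: cumulative area tracks 1 - cos(angle)
  hemi <- make_hemisphere()
  cv3 <- cumulative_area_curve(hemi)
  analytic <- (1 - cos(cv3$angle * pi / 180)) / (1 - cos(pi / 2))
  expect_lt(max(abs(cv3$area / cv3$total - analytic)), 0.01)

  expect_error(cumulative_area_curve(
    triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))), "empty")
})

test_that("threshold determination finds the smallest sufficient angle", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                      rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  cv <- cumulative_area_curve(sq)
  expect_equal(determine_threshold(cv, 100), 0)

  # curve reaching the measured area exactly at the 45-degree bin
  t20 <- rigid_transform(
    triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(20))
  t45 <- rigid_transform(
    triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(45))
  t80 <- rigid_transform(
    triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(80))
  cv2 <- cumulative_area_curve(phenomesh:::merge_meshes(list(t20, t45, t80)))
  expect_equal(determine_threshold(cv2, 100), 45, tolerance = 1e-9)

  # shortfall: the curve never reaches the measured area
  expect_warning(t <- determine_threshold(cv, 125), "short")
  expect_equal(t, 90)
  expect_error(determine_threshold(cv, -1), "positive")
})

test_that("region classification partitions the area and matches the spherical cap", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                      rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  rr <- classify_regions(sq, measured_area = 100)
  expect_equal(rr$stable_frac, 1)
  expect_equal(rr$undetected_frac, 0)

  # detected 98 of measured 100: undetected 2%, stable 98%
  sq98 <- triangle_mesh(rbind(c(0, 0, 0), c(9.8, 0, 0), c(9.8, 10, 0),
                              c(0, 10, 0)),
                        rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  rr2 <- classify_regions(sq98, measured_area = 100)
  expect_equal(rr2$undetected_frac, 0.02, tolerance = 1e-9)
  expect_equal(rr2$stable_frac, 0.98, tolerance = 1e-9)

  # hemisphere at T = 45: stable fraction is the spherical cap 1 - cos(45)
  hemi <- make_hemisphere()
  area <- sum(face_areas(hemi))
  rr3 <- classify_regions(hemi, measured_area = area, threshold = 45)
  expect_equal(rr3$stable_frac, 1 - cos(pi / 4), tolerance = 0.01)

  # invariants: partition of detected area, fractions sum to one
  expect_equal(rr3$stable_area + rr3$unstable_area, rr3$detected_area)
  expect_equal(rr3$stable_frac + rr3$unstable_frac + rr3$undetected_frac, 1,
               tolerance = 1e-9)

  # invariance under rigid Z-rotation
  rr4 <- classify_regions(rigid_transform(hemi, rotation_z(77)),
                          measured_area = area, threshold = 45)
  expect_equal(rr4$stable_frac, rr3$stable_frac, tolerance = 1e-9)

  # boundary faces exactly at T count as stable
  t45 <- rigid_transform(
    triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1L, 2L, 3L))), rotation_x(45))
  rr5 <- classify_regions(t45, measured_area = sum(face_areas(t45)))
  expect_equal(rr5$stable_frac, 1, tolerance = 1e-9)
})

test_that("undetected fraction shrinks as detection grows", {
  hemi <- make_hemisphere(n_phi = 10L, n_theta = 20L)
  area <- sum(face_areas(hemi))
  fracs <- vapply(c(50, 100, 150, 200), function(k) {
    sub <- triangle_mesh(hemi$vertices, hemi$faces[seq_len(k), , drop = FALSE])
    classify_regions(sub, measured_area = area)$undetected_frac
  }, 0)
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("optimum VZA selection applies the three criteria", {
  fake_report <- function(camera, vza, stable, unstable, undetected) {
    structure(list(stable_area = stable, unstable_area = unstable,
                   undetected_area = undetected,
                   detected_area = stable + unstable,
                   measured_area = 100, threshold = 45,
                   stable_frac = stable / 100, unstable_frac = unstable / 100,
                   undetected_frac = undetected / 100,
                   camera = camera, vza = vza),
              class = "region_report")
  }
  # the regime described for the single-leaf sweep: C2-C6 pass, the nadir
  # and near-horizontal cameras fail on undetected or unstable area
  vals <- list(
    c(80, 15, 5), c(97, 2, 1), c(98, 1.5, 0.5), c(99, 0.7, 0.3),
    c(97.5, 1.7, 0.8), c(96, 2.2, 1.8), c(90, 5.2, 4.8), c(85, 10.7, 4.3),
    c(70, 25, 5), c(60, 30, 10))
  reports <- lapply(seq_along(vals), function(i)
    fake_report(paste0("C", i), 12 * (i - 1), vals[[i]][1], vals[[i]][2],
                vals[[i]][3]))
  sel <- select_optimum_vzas(reports)
  expect_identical(sel$cameras, paste0("C", 2:6))
  expect_equal(sel$vza_range, c(12, 60))

  # all pass / all fail
  all_good <- lapply(1:3, function(i)
    fake_report(paste0("C", i), 12 * (i - 1), 99, 0.5, 0.5))
  expect_length(select_optimum_vzas(all_good)$cameras, 3L)
  all_bad <- lapply(1:3, function(i)
    fake_report(paste0("C", i), 12 * (i - 1), 50, 25, 25))
  expect_warning(sel0 <- select_optimum_vzas(all_bad), "no camera")
  expect_length(sel0$cameras, 0L)
})

test_that("threshold rises from the cleanest to the noisiest model", {
  sc <- make_leaf_scene(resolution = 3)
  sch <- turntable_schedule()
  measured <- sc$leaf$ground_truth$area_cm2 * 100
  clean <- reconstruct_single_vza(sc$scene, sc$rig, 4, sch,
                                  noise_model(seed = 2))
  noisy <- reconstruct_single_vza(sc$scene, sc$rig, 4, sch,
                                  noise_model(sigma0 = 5, seed = 2))
  t_clean <- determine_threshold(cumulative_area_curve(clean, organ = "L1"),
                                 measured)
  t_noisy <- suppressWarnings(
    determine_threshold(cumulative_area_curve(noisy, organ = "L1"), measured))
  expect_lt(t_clean, 30)
  expect_gt(t_noisy, t_clean)
})
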