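test_that("an unoccluded horizontal leaf is visible from the nadir camera in every frame", {
  sc <- make_leaf_scene()
  sch <- turntable_schedule()
  vr <- visibility_runs(sc$scene, sc$rig, 1, sch)
  leaf_faces <- which(sc$scene$labels == "L1")
  expect_true(all(vr$visible[leaf_faces, ]))
  expect_true(all(vr$run[leaf_faces] == 41L))
  # overlap counts: 41 for one camera, 5 * 41 for C2-C6
  expect_equal(unique(overlap_map(sc$scene, sc$rig, 1, sch)[leaf_faces]), 41L)
  expect_equal(unique(overlap_map(sc$scene, sc$rig, 2:6, sch)[leaf_faces]),
               205L)
})

test_that("a downward face under the soil plate with all cameras above is never seen", {
  sc <- make_leaf_scene()
  below <- triangle_mesh(rbind(c(-5, -5, -10), c(5, -5, -10), c(0, 5, -10)),
                         rbind(c(1L, 2L, 3L)), labels = "probe")
  scene <- phenomesh:::merge_meshes(list(sc$scene, below))
  sch <- turntable_schedule()
  idx <- which(scene$labels == "probe")
  for (cam in c(1L, 4L)) {
    vr <- visibility_runs(scene, sc$rig, cam, sch)
    expect_equal(vr$run[idx], 0L)
  }
})

test_that("occluded visibility matches the independent pure-R ray caster", {
  # faces behind a vertical cylinder, seen from a side-ish camera
  sch <- turntable_schedule()
  set.seed(42)
  for (s in 1:6) {
    cyl <- make_cylinder_mesh(8 + runif(1, 0, 4), 0, 60, sides = 16L)
    probe <- triangle_mesh(rbind(c(25, -3, 30), c(25, 3, 30), c(28, 0, 33)),
                           rbind(c(1L, 2L, 3L)))
    probe <- rigid_transform(probe, rotation_z(runif(1, 0, 360)))
    scene <- phenomesh:::merge_meshes(list(cyl, probe))
    rig <- camera_rig(center = c(0, 0, 30))
    cam <- sample(5:8, 1)
    idx <- n_faces(scene)  # the probe face
    vr <- visibility_runs(scene, rig, cam, sch)
    # exact agreement pose by pose with the R oracle at the same 40 poses
    oracle40 <- r_visibility(scene, rig$positions[cam, ], sch$poses, idx)
    expect_identical(as.vector(vr$visible[idx, ]), as.vector(oracle40[1, ]))
    # fraction agreement with a 1-degree oracle; a convex occluder plus the
    # incidence cutoff gives at most ~4 transition poses, so the 9-degree
    # sampling can differ from the fine sweep by at most ~4/40
    oracle1 <- r_visibility(scene, rig$positions[cam, ], 0:359, idx)
    expect_lt(abs(mean(vr$visible[idx, ]) - mean(oracle1[1, ])), 0.105)
    # roughly half the rotation is blocked by the cylinder
    expect_gt(mean(oracle1[1, ]), 0.2)
    expect_lt(mean(oracle1[1, ]), 0.8)
  }
})

test_that("the consecutive-frame rule gates detection at n_min", {
  sc <- make_leaf_scene()
  sch <- turntable_schedule()
  nm <- noise_model(seed = 3)
  vr <- visibility_runs(sc$scene, sc$rig, 4, sch)
  pm <- reconstruct_single_vza(sc$scene, sc$rig, 4, sch, nm, visibility = vr)
  # unoccluded leaf at an optimum angle: every leaf face detected
  leaf_faces <- which(sc$scene$labels == "L1")
  expect_true(all(leaf_faces %in% pm$faces))
  # a synthetic visibility pattern with an 8-frame run is below the default
  # threshold, a 9-frame run passes
  v8 <- rep(FALSE, 40); v8[1:8] <- TRUE
  expect_equal(phenomesh:::.cyclic_run(v8)$len, 8L)
  v9 <- rep(FALSE, 40); v9[5:13] <- TRUE
  expect_equal(phenomesh:::.cyclic_run(v9)$len, 9L)
  # wrap-around runs are counted cyclically
  vw <- rep(FALSE, 40); vw[c(37:40, 1:5)] <- TRUE
  expect_equal(phenomesh:::.cyclic_run(vw)$len, 9L)
  expect_equal(phenomesh:::.cyclic_run(vw)$start, 37L)
})

test_that("a vertex over the rotation axis has unconstrained depth under the nadir camera", {
  sc <- make_leaf_scene()
  sch <- turntable_schedule()
  nm <- noise_model(seed = 1)
  pm <- reconstruct_single_vza(sc$scene, sc$rig, 1, sch, nm)
  # the nadir camera never moves relative to the plant: parallax is zero
  # everywhere and every detected vertex saturates at sigma_max
  expect_true(all(pm$sigma[!is.na(pm$sigma)] == nm$sigma_max))
  # an oblique camera constrains depth: sigma far below sigma_max
  pm4 <- reconstruct_single_vza(sc$scene, sc$rig, 4, sch, nm)
  expect_lt(max(pm4$sigma, na.rm = TRUE), 0.5)
})

test_that("parallax equals the closed-form ray geometry for a full run", {
  # vertex 50 mm off axis, VZA 36 deg, visible at every pose: the widest
  # triangulation baseline over the relative camera orbit, computed here
  # independently from plain trigonometry
  rig <- camera_rig(center = c(0, 0, 0))
  sch <- turntable_schedule()
  v <- c(50, 0, 0)
  cams <- phenomesh:::.pose_camera_positions(rig, 4, sch)
  U <- cams - matrix(v, nrow(cams), 3, byrow = TRUE)
  U <- U / sqrt(rowSums(U * U))
  theta_pkg <- acos(min(U %*% t(U)))
  # oracle: camera orbit at radius R sin(a), height R cos(a); max angle
  # subtended at the vertex over all pose pairs
  R <- 1000; a <- 36 * pi / 180
  ang <- (0:39) * 9 * pi / 180
  P <- cbind(R * sin(a) * cos(ang), -R * sin(a) * sin(ang), R * cos(a))
  theta_oracle <- 0
  for (i in 1:39) for (j in (i + 1):40) {
    ui <- (P[i, ] - v) / sqrt(sum((P[i, ] - v)^2))
    uj <- (P[j, ] - v) / sqrt(sum((P[j, ] - v)^2))
    theta_oracle <- max(theta_oracle, acos(min(1, sum(ui * uj))))
  }
  expect_equal(theta_pkg, theta_oracle, tolerance = 1e-9)
})

test_that("reconstruction is deterministic and occluder removal is monotone", {
  sc <- make_leaf_scene()
  sch <- turntable_schedule()
  nm <- noise_model(seed = 9)
  a <- reconstruct_single_vza(sc$scene, sc$rig, 3, sch, nm)
  b <- reconstruct_single_vza(sc$scene, sc$rig, 3, sch, nm)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)

  # removing an occluder never decreases a run or an overlap count
  cyl <- make_cylinder_mesh(10, 0, 60, sides = 12L)
  probe <- triangle_mesh(rbind(c(30, -4, 30), c(30, 4, 30), c(34, 0, 34)),
                         rbind(c(1L, 2L, 3L)))
  with_occ <- phenomesh:::merge_meshes(list(cyl, probe))
  rig <- camera_rig(center = c(0, 0, 30))
  i_occ <- n_faces(with_occ)
  run_occ <- visibility_runs(with_occ, rig, 6, sch)$run[i_occ]
  run_free <- visibility_runs(probe, rig, 6, sch)$run[1]
  expect_gte(run_free, run_occ)
  ov_occ <- overlap_map(with_occ, rig, 4:6, sch)[i_occ]
  ov_free <- overlap_map(probe, rig, 4:6, sch)[1]
  expect_gte(ov_free, ov_occ)
})

test_that("a short schedule with n_min above the frame count detects nothing", {
  sc <- make_leaf_scene(resolution = 5)
  sch <- suppressWarnings(turntable_schedule(n_frames = 5))
  nm <- noise_model(n_min = 9, seed = 1)
  expect_warning(pm <- reconstruct_single_vza(sc$scene, sc$rig, 4, sch, nm),
                 "n_min")
  expect_length(pm$faces, 0L)
})
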