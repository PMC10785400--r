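span_protein <- function() {
  make_protein_atoms(rbind(c(0, 0, 0), c(25, 5, 5), c(12, 2, 3)))
}

test_that("grid dimensions follow the padded bounding box", {
  g <- build_grid(span_protein(), resolution = 10, padding = 0)
  expect_equal(g$dims, c(3L, 1L, 1L))
  single <- build_grid(make_protein_atoms(rbind(c(1, 1, 1))), padding = 0)
  expect_equal(single$dims, c(1L, 1L, 1L))
  g5 <- build_grid(span_protein(), resolution = 5, padding = 0)
  expect_equal(g5$dims, c(5L, 1L, 1L))
  expect_error(build_grid(span_protein(), resolution = 0), "positive")
  # every heavy atom lies inside the grid
  g_pad <- build_grid(span_protein(), padding = 5)
  idx <- assign_voxel(cbind(span_protein()$x, span_protein()$y,
                            span_protein()$z), g_pad)
  expect_true(all(idx >= 0))
  expect_true(all(sweep(idx, 2, g_pad$dims, "<")))
})

test_that("voxel assignment uses half-open boxes and clamps outsiders", {
  g <- build_grid(make_protein_atoms(rbind(c(0, 0, 0), c(29, 29, 29))),
                  resolution = 10, padding = 0)
  expect_equal(unname(assign_voxel(c(5, 5, 5), g)[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(assign_voxel(c(10, 0, 0), g)[1, ]), c(1L, 0L, 0L))
  expect_warning(out <- assign_voxel(c(-1, 0, 0), g), "clamped")
  expect_equal(unname(out[1, ]), c(0L, 0L, 0L))
  expect_warning(hi <- assign_voxel(c(500, 5, 5), g), "clamped")
  expect_equal(unname(hi[1, ]), c(2L, 0L, 0L))
})

toy_report <- function() {
  pose <- function(p, k, xyz, score = -5) {
    atoms <- tibble::tibble(element = "C", x = xyz[1], y = xyz[2], z = xyz[3],
                            mass = 12.0107)
    tibble::tibble(program = p, pose_id = k, score = score,
                   x = xyz[1], y = xyz[2], z = xyz[3], atoms = list(atoms))
  }
  poses <- dplyr::bind_rows(
    pose("vina", 1, c(3, 3, 3), -7), pose("vina", 2, c(4, 4, 4), -6),
    pose("vina", 3, c(6, 6, 6), -8),
    pose("plants", 1, c(15, 5, 5), -90))
  cavities <- tibble::tibble(
    tool = "fpocket", cavity_id = c(2L, 5L),
    x = c(3, 6), y = c(3, 6), z = c(3, 6),
    descriptors = list(c(druggability_score = 0.8),
                       c(druggability_score = 0.2)))
  new_report("toy", poses, cavities, failures = "zdock")
}

test_that("featurization counts, distances and cavity ranks are correct", {
  prot <- make_protein_atoms(rbind(c(0, 0, 0), c(29, 29, 29)))
  g <- build_grid(prot, resolution = 10, padding = 0)
  tab <- featurize_target(g, toy_report())
  expect_equal(nrow(tab), 27)
  r0 <- tab[tab$ix == 0 & tab$iy == 0 & tab$iz == 0, ]
  expect_equal(r0$sampled_pose_number_vina_at_location, 3)
  expect_equal(r0$vina_best_score, -8)  # energy-like: minimum
  # nearest of the three vina poses to the (5,5,5) center
  expect_equal(r0$vina_distance, sqrt(3), tolerance = 1e-10)
  expect_equal(r0$Fpocket_min_pose_id, 2)
  expect_equal(r0$Fpocket_druggability_score, 0.8)
  # plants pose exactly at the (15,5,5) center of voxel (1,0,0)
  r1 <- tab[tab$ix == 1 & tab$iy == 0 & tab$iz == 0, ]
  expect_equal(r1$plants_distance, 0)
  # failed program yields missing features everywhere
  expect_true(all(is.na(tab$sampled_pose_number_zdock_at_location)))
  expect_true(all(is.na(tab$zdock_best_score)))
})

test_that("zdock best score is the maximum (higher is better)", {
  pose <- function(k, score) {
    atoms <- tibble::tibble(element = "C", x = 1, y = 1, z = 1, mass = 12.0107)
    tibble::tibble(program = "zdock", pose_id = k, score = score,
                   x = 1, y = 1, z = 1, atoms = list(atoms))
  }
  rep <- new_report("t", dplyr::bind_rows(pose(1, 10), pose(2, 14)))
  g <- build_grid(make_protein_atoms(rbind(c(0, 0, 0), c(9, 9, 9))), padding = 0)
  tab <- featurize_target(g, rep)
  expect_equal(tab$zdock_best_score[tab$ix == 0], 14)
})

test_that("every pose lands in exactly one voxel (partition property)", {
  set.seed(11)
  for (k in 1:5) {
    cfg <- scenario_config(n_targets = 1, seed = k,
                           program_failure_rate = 0)
    tg <- generate_target(cfg, 1)
    g <- build_grid(tg$protein)
    tab <- featurize_target(g, tg$report)
    for (p in c("vina", "plants", "galaxydock", "zdock")) {
      col <- paste0("sampled_pose_number_", p, "_at_location")
      expect_equal(sum(tab[[col]], na.rm = TRUE),
                   sum(tg$report$poses$program == p))
    }
    # voxels fed only by in-bounds poses obey the half-diagonal bound
    for (p in c("vina", "plants", "galaxydock", "zdock")) {
      sub <- tg$report$poses[tg$report$poses$program == p, ]
      if (nrow(sub) == 0) next
      pts <- cbind(sub$x, sub$y, sub$z)
      raw <- floor(sweep(sweep(pts, 2, g$origin), 2, g$resolution, "/"))
      inb <- rowSums(raw < 0 | sweep(raw, 2, g$dims, ">=")) == 0
      idx <- suppressWarnings(assign_voxel(pts, g))
      clamped_keys <- unique(paste(idx[, 1], idx[, 2], idx[, 3])[!inb])
      col <- paste0(p, "_distance")
      sel <- !is.na(tab[[col]]) &
        !(paste(tab$ix, tab$iy, tab$iz) %in% clamped_keys)
      expect_true(all(tab[[col]][sel] <= sqrt(3) / 2 * g$resolution + 1e-9))
    }
  }
})

test_that("featurization is translation-equivariant", {
  cfg <- scenario_config(n_targets = 1, seed = 3)
  tg <- generate_target(cfg, 1)
  t_vec <- c(13.7, -8.2, 21.5)
  shift_struct <- function(s) {
    s$x <- s$x + t_vec[1]; s$y <- s$y + t_vec[2]; s$z <- s$z + t_vec[3]; s
  }
  rep2 <- tg$report
  rep2$poses$x <- rep2$poses$x + t_vec[1]
  rep2$poses$y <- rep2$poses$y + t_vec[2]
  rep2$poses$z <- rep2$poses$z + t_vec[3]
  rep2$cavities$x <- rep2$cavities$x + t_vec[1]
  rep2$cavities$y <- rep2$cavities$y + t_vec[2]
  rep2$cavities$z <- rep2$cavities$z + t_vec[3]
  tab1 <- featurize_target(build_grid(tg$protein), tg$report)
  tab2 <- featurize_target(build_grid(shift_struct(tg$protein)), rep2)
  expect_equal(tab1[, c("ix", "iy", "iz")], tab2[, c("ix", "iy", "iz")],
               ignore_attr = TRUE)
  fc <- feature_cols(tab1)
  expect_equal(as.data.frame(tab1[, fc]), as.data.frame(tab2[, fc]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(tab2$cx, tab1$cx + t_vec[1], tolerance = 1e-8)
})

test_that("empty-voxel filtering keeps only occupied rows and is idempotent", {
  prot <- make_protein_atoms(rbind(c(0, 0, 0), c(29, 29, 29)))
  g <- build_grid(prot, resolution = 10, padding = 0)
  tab <- featurize_target(g, toy_report())
  kept <- filter_empty(tab)
  # all vina poses and both cavities land in voxel (0,0,0); plants in (1,0,0)
  expect_equal(nrow(kept), 2)
  expect_equal(filter_empty(kept), kept)
  # cavity-only report: cavity-bearing voxels retained
  cav_only <- new_report("c", cavities = toy_report()$cavities)
  tab_c <- featurize_target(g, cav_only)
  expect_equal(nrow(filter_empty(tab_c)), 1)
  all_fail <- new_report("f", failures = c(docking_programs(), cavity_tools()))
  expect_error(filter_empty(featurize_target(g, all_fail)), "empty")
})

test_that("labelling marks the ligand's voxel positive, re-inserting if needed", {
  prot <- make_protein_atoms(rbind(c(0, 0, 0), c(29, 29, 29)))
  g <- build_grid(prot, resolution = 10, padding = 0)
  tab <- filter_empty(featurize_target(g, toy_report()))
  lab <- label_rows(tab, c(5, 5, 5))
  expect_equal(sum(lab$label == "positive"), 1)
  expect_equal(lab$label[lab$ix == 0 & lab$iy == 0 & lab$iz == 0], "positive")
  expect_true(all(lab$label[-which(lab$label == "positive")] == "negative"))
  # ligand centroid in a voxel nothing touched: row re-inserted
  lab2 <- label_rows(tab, c(25, 25, 25))
  expect_equal(nrow(lab2), nrow(tab) + 1)
  new_row <- lab2[lab2$ix == 2 & lab2$iy == 2 & lab2$iz == 2, ]
  expect_equal(new_row$label, "positive")
  expect_true(is.na(new_row$vina_distance))
  expect_equal(new_row$sampled_pose_number_vina_at_location, 0)
})

test_that("mean imputation fills missing cells with training means only", {
  t1 <- tibble::tibble(target_id = "a", ix = 0L, iy = 0L, iz = 0L,
                       cx = 5, cy = 5, cz = 5, label = "negative",
                       f1 = 1, f2 = NA_real_)
  t2 <- tibble::tibble(target_id = "b", ix = 0L, iy = 0L, iz = 0L,
                       cx = 5, cy = 5, cz = 5, label = "negative",
                       f1 = 3, f2 = NA_real_)
  means <- suppressWarnings(fit_impute(list(t1, t2)))
  expect_equal(unname(means["f1"]), 2)
  expect_equal(unname(means["f2"]), 0)  # fully missing -> 0, flagged
  expect_equal(attr(means, "all_missing"), "f2")
  out <- apply_impute(t1, means)
  expect_equal(out$f2, 0)
  expect_equal(attr(out, "imputed")$feature, "f2")
  # inference-time table uses the training means, not its own
  t3 <- t1; t3$f1 <- NA_real_
  expect_equal(apply_impute(t3, means)$f1, 2)
  # no missing values: unchanged, and idempotent
  done <- apply_impute(out, means)
  expect_equal(as.data.frame(done), as.data.frame(out), ignore_attr = TRUE)
})
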