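scored_fixture <- function() {
  tibble::tibble(
    target_id = "t",
    ix = c(0L, 1L, 2L), iy = 0L, iz = 0L,
    cx = c(5, 15, 25), cy = 5, cz = 5,
    label = "unlabeled",
    total_pose_count = c(4, 9, 1),
    score = c(0.9, 0.2, 0.2)
  )
}

test_that("voxels rank by score with pose-count and index tie-breaks", {
  r <- rank_voxels(scored_fixture())
  expect_equal(r$ix, c(0L, 1L, 2L))  # 0.9 first; tie 0.2/0.2 -> more poses
  tie <- scored_fixture()
  tie$score <- 0.5
  tie$total_pose_count <- c(1, 1, 1)
  r2 <- rank_voxels(tie)
  expect_equal(r2$ix, c(0L, 1L, 2L))  # full tie -> lexicographic index
  single <- rank_voxels(scored_fixture()[2, ])
  expect_equal(single$rank, 1L)
  expect_error(rank_voxels(scored_fixture()[0, ]), "no scored voxels")
})

cavity_fixture <- function() {
  tibble::tibble(
    tool = c("fpocket", "p2rank", "fpocket"),
    cavity_id = c(1L, 1L, 2L),
    x = c(3, 9, 26), y = c(0, 0, 5), z = c(0, 0, 5),
    descriptors = list(numeric(), numeric(), numeric())
  )
}

test_that("the top voxel maps to the nearest cavity deterministically", {
  vox <- tibble::tibble(rank = 1L, score = 0.9, ix = 0L, iy = 0L, iz = 0L,
                        cx = 0, cy = 0, cz = 0)
  pred <- map_to_cavity(vox, cavity_fixture())
  expect_equal(pred$site_x, 3)
  expect_equal(pred$provenance, "fpocket#1")
  # cavity exactly at the voxel center wins with distance 0
  cavs <- cavity_fixture()
  cavs$x[2] <- 0
  pred0 <- map_to_cavity(vox, cavs)
  expect_equal(pred0$cavity_distance, 0)
  expect_equal(pred0$tool, "p2rank")
  # invariant to cavity list order
  pred_rev <- map_to_cavity(vox, cavity_fixture()[c(3, 1, 2), ])
  expect_equal(pred_rev$provenance, pred$provenance)
  # distance tie: smaller cavity_id, then fpocket before p2rank
  tie_cavs <- tibble::tibble(tool = c("p2rank", "fpocket"),
                             cavity_id = c(1L, 1L),
                             x = c(2, -2), y = 0, z = 0,
                             descriptors = list(numeric(), numeric()))
  tie_pred <- map_to_cavity(vox, tie_cavs)
  expect_equal(tie_pred$tool, "fpocket")
  expect_warning(fallback <- map_to_cavity(vox, cavity_fixture()[0, ]),
                 "voxel center")
  expect_equal(fallback$provenance, "voxel-only")
  expect_equal(c(fallback$site_x, fallback$site_y, fallback$site_z), c(0, 0, 0))
})

test_that("top-k sites dedup cavities while walking the ranking", {
  ranked <- rank_voxels(scored_fixture())
  k1 <- top_k_sites(ranked, cavity_fixture(), k = 1)
  expect_equal(nrow(k1), 1)
  expect_equal(k1$provenance,
               map_to_cavity(ranked[1, ], cavity_fixture())$provenance)
  # voxels 0 and 1 both map to fpocket#1; k = 2 must find a second cavity
  k2 <- top_k_sites(ranked, cavity_fixture(), k = 2)
  expect_equal(nrow(k2), 2)
  expect_false(k2$provenance[1] == k2$provenance[2])
  expect_warning(k9 <- top_k_sites(ranked, cavity_fixture(), k = 9),
                 "distinct cavity")
  expect_lte(nrow(k9), 3)
})

test_that("docking plans echo the site into a 15 A box and config stubs", {
  vox <- tibble::tibble(rank = 1L, score = 0.8, ix = 0L, iy = 0L, iz = 0L,
                        cx = 0, cy = 0, cz = 0)
  cavs <- tibble::tibble(tool = "fpocket", cavity_id = 1L,
                         x = 1, y = 2, z = 3, descriptors = list(numeric()))
  site <- map_to_cavity(vox, cavs)
  dir <- tempfile("plan")
  plan <- make_docking_plan(site, dir = dir)
  expect_equal(unname(plan$center), c(1, 2, 3))
  expect_equal(plan$extent, 15)
  expect_equal(plan$program_order, c("plants", "vina", "galaxydock"))
  conf <- readLines(file.path(dir, "vina.conf"))
  expect_true(any(grepl("center_x = 1.000", conf, fixed = TRUE)))
  expect_true(any(grepl("size_x = 15", conf, fixed = TRUE)))
  expect_true(file.exists(file.path(dir, "plants_stub.json")))
  # custom extent and order
  plan20 <- make_docking_plan(site, extent = 20, program_order = "vina")
  expect_equal(plan20$extent, 20)
  expect_equal(plan20$program_order, "vina")
  expect_error(make_docking_plan(site, extent = -1), "positive")
})

test_that("final pose selection respects polarity and fallback order", {
  mk <- function(program, scores) {
    purrr::imap_dfr(scores, function(s, k) {
      tibble::tibble(program = program, pose_id = k, score = s,
                     x = k, y = 0, z = 0,
                     atoms = list(tibble::tibble(element = "C", x = k,
                                                 y = 0, z = 0, mass = 12)))
    })
  }
  plants <- mk("plants", c(-80, -95, -60))
  expect_equal(select_final_pose(plants)$score, -95)
  vina <- mk("vina", c(-7.1, -6.2))
  expect_equal(select_final_pose(dplyr::bind_rows(plants, vina))$program,
               "plants")
  expect_equal(select_final_pose(vina)$score, -7.1)  # plants absent -> vina
  zd <- mk("zdock", c(10, 15, 12))
  expect_equal(select_final_pose(zd, program_order = "zdock")$score, 15)
  single <- mk("plants", -50)
  expect_equal(select_final_pose(single)$pose_id, 1L)
  expect_error(select_final_pose(mk("plants", -1)[0, ]), "failed")
})

test_that("fixed inputs and model give identical site predictions", {
  targets <- make_targets(6, seed = 9)
  tabs <- purrr::map(targets, "table")
  means <- suppressWarnings(fit_impute(tabs))
  tabs <- purrr::map(tabs, ~ apply_impute(.x, means))
  model <- train_site_scorer(
    tabs, stack_config(bags_per_learner = 1, folds_for_oof = 2,
                       stack_layers = 1, seed = 2))
  tg <- targets[[3]]
  p1 <- predict_site(model, list(table = apply_impute(tg$table, means),
                                 report = tg$report))
  p2 <- predict_site(model, list(table = apply_impute(tg$table, means),
                                 report = tg$report))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})
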