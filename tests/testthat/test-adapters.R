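random_report <- function(seed, target_id = paste0("t", seed)) {
  set.seed(seed)
  progs <- sample(docking_programs(), sample(1:4, 1))
  poses <- purrr::map_dfr(progs, function(p) {
    purrr::map_dfr(seq_len(sample(1:5, 1)), function(k) {
      atoms <- tibble::tibble(element = sample(c("C", "N", "O"), 4, TRUE),
                              x = rnorm(4), y = rnorm(4), z = rnorm(4))
      atoms$mass <- voxdock:::element_mass(atoms$element)
      cen <- unname(centroid(atoms))
      tibble::tibble(program = p, pose_id = k,
                     score = ifelse(runif(1) < 0.2, NA_real_, rnorm(1)),
                     x = cen[1], y = cen[2], z = cen[3], atoms = list(atoms))
    })
  })
  cavities <- purrr::map_dfr(sample(cavity_tools(), sample(1:2, 1)), function(tl) {
    purrr::map_dfr(seq_len(sample(1:3, 1)), function(k) {
      tibble::tibble(tool = tl, cavity_id = k, x = rnorm(1), y = rnorm(1),
                     z = rnorm(1),
                     descriptors = list(c(score = rnorm(1), depth = runif(1))))
    })
  })
  failed <- setdiff(c(docking_programs(), cavity_tools()),
                    c(unique(poses$program), unique(cavities$tool)))
  new_report(target_id, poses, cavities, failures = failed)
}

test_that("interchange write/read is the identity on randomized reports", {
  for (seed in c(1, 7, 23)) {
    rep <- random_report(seed)
    path <- tempfile(fileext = ".json")
    write_interchange(rep, path)
    back <- read_interchange(path)
    expect_equal(back$target_id, rep$target_id)
    expect_equal(back$failures, rep$failures)
    expect_equal(back$poses$program, rep$poses$program)
    expect_equal(back$poses$pose_id, rep$poses$pose_id)
    expect_equal(back$poses$score, rep$poses$score)
    expect_equal(back$poses$x, rep$poses$x, tolerance = 1e-12)
    expect_equal(purrr::map(back$poses$atoms, as.data.frame),
                 purrr::map(rep$poses$atoms, as.data.frame),
                 tolerance = 1e-12)
    expect_equal(back$cavities$cavity_id, rep$cavities$cavity_id)
    expect_equal(purrr::map(back$cavities$descriptors, sort),
                 purrr::map(rep$cavities$descriptors, sort), tolerance = 1e-12)
  }
})

test_that("degenerate all-failed report round-trips with six failures", {
  rep <- new_report("dead", failures = c(docking_programs(), cavity_tools()))
  path <- tempfile(fileext = ".json")
  write_interchange(rep, path)
  back <- read_interchange(path)
  expect_equal(nrow(back$poses), 0)
  expect_equal(nrow(back$cavities), 0)
  expect_length(back$failures, 6)
})

test_that("a program cannot both report records and be failed", {
  pose <- random_report(3)$poses[1, ]
  expect_error(new_report("x", pose, failures = pose$program[1]),
               "both with records and as failures")
})

test_that("interchange validation names the offending field", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "something-else/9", target_id = "x"),
                       path, auto_unbox = TRUE)
  expect_error(read_interchange(path), "schema")
  jsonlite::write_json(
    list(schema = "voxdock-interchange/1", target_id = "x",
         poses = list(list(program = "vina"))),
    path, auto_unbox = TRUE)
  expect_error(read_interchange(path), "pose_id")
})

fpocket_fixture <- function() {
  dir <- tempfile("fpocket")
  dir.create(file.path(dir, "pockets"), recursive = TRUE)
  writeLines(c(
    "Pocket 1 :",
    "\tScore : \t0.345",
    "\tDruggability Score : \t0.612",
    "\tNumber of Alpha Spheres : \t41",
    "\tLocal hydrophobic density Score : \t27.3",
    "\tWeird line without value : \tabc",
    "Pocket 2 :",
    "\tScore : \t0.101",
    "\tDruggability Score : \t0.205",
    "\tNumber of Alpha Spheres : \t12",
    "\tLocal hydrophobic density Score : \t11.0"
  ), file.path(dir, "protein_info.txt"))
  writeLines(c(
    "ATOM      1    O STP     1       1.000   1.000   1.000  0.00  3.25",
    "ATOM      2    C STP     1       3.000   1.000   1.000  0.00  3.10"
  ), file.path(dir, "pockets", "pocket1_vert.pqr"))
  writeLines(c(
    "ATOM      1    C STP     2      10.000  10.000  10.000  0.00  3.00"
  ), file.path(dir, "pockets", "pocket2_vert.pqr"))
  dir
}

test_that("fpocket directories parse into ranked cavity records", {
  dir <- fpocket_fixture()
  recs <- suppressWarnings(parse_fpocket_dir(dir))
  expect_equal(recs$cavity_id, c(1L, 2L))
  d1 <- recs$descriptors[[1]]
  expect_equal(unname(d1["number_of_alpha_sphere"]), 41)
  expect_equal(unname(d1["druggability_score"]), 0.612)
  expect_false("weird_line_without_value" %in% names(d1))
  expect_warning(parse_fpocket_dir(dir), "unparseable")
  # pocket 1 centroid: mass centre of one O and one C at x = 1 and 3
  wO <- 15.9994 / (15.9994 + 12.0107)
  expect_equal(recs$x[1], 1 + 2 * (1 - wO), tolerance = 1e-4)
  expect_equal(recs$x[2], 10)
  expect_error(parse_fpocket_dir(tempfile()), "not found")
})

test_that("p2rank CSVs parse ranks, centers and extra descriptor columns", {
  path <- write_fixture(c(
    "name, rank, score, probability, center_x, center_y, center_z, extra_col",
    "pocket1, 1, 22.5, 0.91, 1.0, 2.0, 3.0, 7.7",
    "pocket2, 2, 10.1, 0.55, 4.0, 5.0, 6.0, 8.8",
    "pocket3, 3, 2.0, 0.10, 7.0, 8.0, 9.0, 9.9"), ".csv")
  recs <- parse_p2rank_csv(path)
  expect_equal(recs$cavity_id, 1:3)
  expect_equal(recs$x, c(1, 4, 7))
  expect_equal(unname(recs$descriptors[[1]]["probability"]), 0.91)
  expect_equal(unname(recs$descriptors[[2]]["extra_col"]), 8.8)

  hdr_only <- write_fixture(
    "name, rank, score, probability, center_x, center_y, center_z", ".csv")
  expect_equal(nrow(parse_p2rank_csv(hdr_only)), 0)

  bad <- write_fixture(c("name, rank, score", "a, 1, 2"), ".csv")
  expect_error(parse_p2rank_csv(bad), "center_x")
})

vina_pdbqt_fixture <- function() {
  write_fixture(c(
    "MODEL 1",
    "REMARK VINA RESULT:    -7.5      0.000      0.000",
    "ATOM      1  C   LIG A   1       1.000   0.000   0.000  1.00  0.00    0.10 C ",
    "ATOM      2  OA  LIG A   1       2.000   0.000   0.000  1.00  0.00   -0.20 OA",
    "ATOM      3  HD  LIG A   1       2.500   0.500   0.000  1.00  0.00    0.15 HD",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:    -6.9      1.200      2.100",
    "ATOM      1  C   LIG A   1       5.000   0.000   0.000  1.00  0.00    0.10 C ",
    "ATOM      2  OA  LIG A   1       6.000   0.000   0.000  1.00  0.00   -0.20 OA",
    "ENDMDL",
    "MODEL 3",
    "ATOM      1  C   LIG A   1       9.000   0.000   0.000  1.00  0.00    0.10 C ",
    "ATOM      2  OA  LIG A   1       9.500   0.000   0.000  1.00  0.00   -0.20 OA",
    "ENDMDL"), ".pdbqt")
}

test_that("vina PDBQT poses parse scores, drop hydrogens, keep order", {
  poses <- parse_vina_pdbqt(vina_pdbqt_fixture())
  expect_equal(poses$pose_id, 1:3)
  expect_equal(poses$score, c(-7.5, -6.9, NA))
  # hydrogens excluded from model 1
  expect_equal(nrow(poses$atoms[[1]]), 2)
  expect_setequal(poses$atoms[[1]]$element, c("C", "O"))
  # no MODEL records -> empty
  empty <- write_fixture("REMARK nothing here", ".pdbqt")
  expect_equal(nrow(parse_vina_pdbqt(empty)), 0)
})

test_that("generic multi-entry pose files parse in order with score table", {
  entry <- function(id, xoff) c(
    "@<TRIPOS>MOLECULE", id, " 2 1 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("  1 C1  %.1f 0.0 0.0 C.3 1 LIG 0.0", xoff),
    sprintf("  2 O1  %.1f 1.2 0.0 O.3 1 LIG 0.0", xoff + 1),
    "@<TRIPOS>BOND", " 1 1 2 1")
  path <- write_fixture(c(entry("p1", 0), entry("p2", 5), entry("p3", 10)),
                        ".mol2")
  poses <- parse_generic_poses(path, "plants", "mol2", scores = c(-80, -95))
  expect_equal(nrow(poses), 3)
  expect_equal(poses$program, rep("plants", 3))
  expect_equal(poses$pose_id, 1:3)
  expect_equal(poses$score, c(-80, -95, NA))

  sdf1 <- write_fixture(ethanol_sdf_text(), ".sdf")
  one <- parse_generic_poses(sdf1, "galaxydock", "sdf")
  expect_equal(nrow(one), 1)
  expect_equal(nrow(one$atoms[[1]]), 3)

  expect_error(parse_generic_poses(path, "not_a_program", "mol2"), "unknown")
})

test_that("parsed pose centroids match recomputation from their atoms", {
  poses <- parse_vina_pdbqt(vina_pdbqt_fixture())
  for (i in seq_len(nrow(poses))) {
    cen <- centroid(poses$atoms[[i]])
    expect_equal(c(poses$x[i], poses$y[i], poses$z[i]), unname(cen),
                 tolerance = 1e-6)
  }
})
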