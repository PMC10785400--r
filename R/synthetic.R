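#' Synthetic blind-docking scenario configuration
#'
#' Generates self-contained targets: a pseudo-atom protein point cloud
#' with one true binding site and several well-separated decoy sites,
#' per-program pose sets whose concentration at the true site is the
#' tunable difficulty knob, per-tool cavity lists with ranks and
#' descriptors, and a rigid crystal ligand at the true site. Defaults
#' emulate the observed behaviour of the real programs: tens to
#' hundreds of poses per program (ZDOCK in the hundreds), a 0-2 %
#' whole-program failure rate, and the easy setting's 0.6 probability
#' that a pose lands at the true site (0.3 is the hard setting).
#'
#' @param n_targets Number of targets.
#' @param protein_radius Protein sphere radius in Angstrom (default 25).
#' @param n_decoy_sites Decoy binding sites per target (default 4).
#' @param program_accuracy Probability a pose lands at the true site:
#'   a single value (default 0.6) or a named per-program vector.
#' @param pose_spread_sigma Gaussian spread of pose centroids around
#'   their site, Angstrom (default 2.5).
#' @param poses_per_program Named vector of pose counts (default vina
#'   9, plants 10, galaxydock 20, zdock 100).
#' @param cavity_noise_sigma Perturbation of cavity centroids, Angstrom
#'   (default 2).
#' @param cavity_true_rank_bias Probability the true site is a tool's
#'   rank-1 cavity (default 0.5).
#' @param program_failure_rate Per-program probability of total failure
#'   (default 0.02).
#' @param score_separation Mean score shift of true-site poses in the
#'   favourable direction, in score units (default 2).
#' @param seed RNG seed; each target's stream is derived from
#'   `(seed, index)`.
#' @return A `vd_scenario_config` list.
#' @export
scenario_config <- function(n_targets = 60, protein_radius = 25,
                            n_decoy_sites = 4, program_accuracy = 0.6,
                            pose_spread_sigma = 2.5,
                            poses_per_program = c(vina = 9, plants = 10,
                                                  galaxydock = 20, zdock = 100),
                            cavity_noise_sigma = 2,
                            cavity_true_rank_bias = 0.5,
                            program_failure_rate = 0.02,
                            score_separation = 2, seed = 0) {
  progs <- docking_programs()
  if (length(program_accuracy) == 1 && is.null(names(program_accuracy))) {
    program_accuracy <- setNames(rep(program_accuracy, length(progs)), progs)
  }
  if (!all(progs %in% names(program_accuracy))) {
    abort("program_accuracy must cover every docking program")
  }
  all_progs <- c(progs, cavity_tools())
  if (length(program_failure_rate) == 1 && is.null(names(program_failure_rate))) {
    program_failure_rate <- setNames(rep(program_failure_rate,
                                         length(all_progs)), all_progs)
  } else {
    full <- setNames(rep(0, length(all_progs)), all_progs)
    full[names(program_failure_rate)] <- program_failure_rate
    program_failure_rate <- full
  }
  stopifnot(all(program_accuracy >= 0 & program_accuracy <= 1),
            pose_spread_sigma > 0, cavity_noise_sigma > 0,
            cavity_true_rank_bias >= 0, cavity_true_rank_bias <= 1,
            all(program_failure_rate >= 0 & program_failure_rate <= 1))
  structure(list(
    n_targets = as.integer(n_targets), protein_radius = protein_radius,
    n_decoy_sites = as.integer(n_decoy_sites),
    program_accuracy = program_accuracy[progs],
    pose_spread_sigma = pose_spread_sigma,
    poses_per_program = poses_per_program,
    cavity_noise_sigma = cavity_noise_sigma,
    cavity_true_rank_bias = cavity_true_rank_bias,
    program_failure_rate = program_failure_rate,
    score_separation = score_separation,
    seed = as.integer(seed)
  ), class = "vd_scenario_config")
}

# rigid 8-heavy-atom ligand template (phenol-like: ring + O + methyl),
# centred so its mass centroid is the origin
ligand_template <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  oxy <- c(2.76, 0, 0.3)
  meth <- c(-2.15, 1.25, -0.3)
  atoms <- tibble::tibble(
    element = c(rep("C", 6), "O", "C"),
    x = c(ring[, 1], oxy[1], meth[1]),
    y = c(ring[, 2], oxy[2], meth[2]),
    z = c(ring[, 3], oxy[3], meth[3]),
    is_hetero = TRUE, residue_name = "LIG"
  )
  bonds <- tibble::tibble(
    i = c(1:6, 1L, 4L), j = c(2:6, 1L, 7L, 8L),
    order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L)
  )
  s <- as_structure(atoms, name = "template_ligand", kind = "ligand",
                    bonds = bonds)
  cen <- centroid(s)
  s$x <- s$x - cen[1]; s$y <- s$y - cen[2]; s$z <- s$z - cen[3]
  s
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

place_ligand <- function(template, at, rotate = TRUE) {
  xyz <- cbind(template$x, template$y, template$z)
  if (rotate) xyz <- xyz %*% t(random_rotation())
  out <- template
  out$x <- xyz[, 1] + at[1]; out$y <- xyz[, 2] + at[2]; out$z <- xyz[, 3] + at[3]
  out
}

# well-separated points on the sphere surface (min pairwise separation)
sample_sites <- function(n, radius, min_sep = 12) {
  pts <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(pts) < n && tries < 5000) {
    tries <- tries + 1
    v <- rnorm(3); v <- v / sqrt(sum(v^2)) * radius
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, v)^2))) >= min_sep) {
      pts <- rbind(pts, v)
    }
  }
  if (nrow(pts) < n) abort("could not place well-separated sites; radius too small")
  pts
}

target_seed <- function(config, index) {
  ((abs(config$seed) %% 100003L) * 20011L + index * 7919L) %% 2147483629L
}

#' Generate one synthetic target
#'
#' Fully deterministic given `(config$seed, index)`.
#'
#' @param config A [scenario_config()].
#' @param index 1-based target index.
#' @return A list with `protein` (a `vd_structure` of carbon
#'   pseudo-atoms), `truth` (list: `target_id`, `true_site`, `decoys`,
#'   `crystal_ligand`) and `report` (a `vd_report`).
#' @export
generate_target <- function(config, index) {
  set.seed(target_seed(config, index))
  target_id <- sprintf("synth%04d", index)
  R <- config$protein_radius

  # pseudo-atom cloud: uniform in the ball, greedily thinned to >= 3 A spacing
  n_cand <- 600
  u <- matrix(rnorm(3 * n_cand), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n_cand)^(1 / 3)
  keep <- c(1L)
  for (i in 2:n_cand) {
    if (min(sqrt(rowSums(sweep(u[keep, , drop = FALSE], 2, u[i, ])^2))) >= 3) {
      keep <- c(keep, i)
    }
  }
  cloud <- u[keep, , drop = FALSE]
  protein <- as_structure(
    tibble::tibble(element = "C", x = cloud[, 1], y = cloud[, 2],
                   z = cloud[, 3], residue_name = "GLY",
                   is_hetero = FALSE),
    name = target_id, kind = "protein")

  sites <- sample_sites(1 + config$n_decoy_sites, R)
  true_site <- sites[1, ]
  decoys <- sites[-1, , drop = FALSE]

  all_progs <- c(docking_programs(), cavity_tools())
  failed <- all_progs[runif(length(all_progs)) <
                      config$program_failure_rate[all_progs]]

  template <- ligand_template()
  poses <- purrr::map_dfr(docking_programs(), function(p) {
    if (p %in% failed) return(empty_poses())
    n_p <- config$poses_per_program[[p]]
    acc <- config$program_accuracy[[p]]
    at_true <- runif(n_p) < acc
    site_idx <- sample(nrow(decoys), n_p, replace = TRUE)
    pol <- score_polarity(p)
    base <- switch(p, vina = -7, plants = -90, galaxydock = -100, zdock = 10)
    purrr::map_dfr(seq_len(n_p), function(k) {
      ctr <- (if (at_true[k]) true_site else decoys[site_idx[k], ]) +
        rnorm(3, 0, config$pose_spread_sigma)
      lig <- place_ligand(template, ctr)
      shift <- if (at_true[k]) config$score_separation else 0
      score <- rnorm(1, base + pol * shift, 1)
      pose_row(p, k, score, lig)
    })
  })

  cavities <- purrr::map_dfr(cavity_tools(), function(tl) {
    if (tl %in% failed) return(empty_cavities())
    centers <- rbind(true_site, decoys) +
      matrix(rnorm(3 * (1 + nrow(decoys)), 0, config$cavity_noise_sigma),
             ncol = 3)
    n_cav <- nrow(centers)
    ranks <- if (runif(1) < config$cavity_true_rank_bias) {
      c(1L, 1L + sample(n_cav - 1L))
    } else sample(n_cav)
    is_true <- c(TRUE, rep(FALSE, n_cav - 1L))
    desc <- purrr::map(seq_len(n_cav), function(i) {
      if (tl == "fpocket") {
        c(druggability_score = min(1, max(0, rnorm(1, ifelse(is_true[i], 0.7, 0.35), 0.15))),
          number_of_alpha_sphere = rpois(1, ifelse(is_true[i], 45, 25)),
          local_hydrophobic_density_score = rnorm(1, ifelse(is_true[i], 30, 20), 5))
      } else {
        sc <- max(0, rnorm(1, ifelse(is_true[i], 20, 8), 3))
        c(score = sc, probability = stats::plogis((sc - 12) / 4))
      }
    })
    tibble::tibble(tool = tl, cavity_id = as.integer(ranks),
                   x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   descriptors = desc) |>
      dplyr::arrange(.data$cavity_id)
  })

  crystal <- place_ligand(template, true_site)
  attr(crystal, "mol_name") <- paste0(target_id, "_ligand")
  truth <- list(target_id = target_id, true_site = unname(true_site),
                decoys = unname(decoys), crystal_ligand = crystal)
  report <- new_report(target_id, poses, cavities, failures = failed)
  list(protein = protein, truth = truth, report = report)
}

#' Write a synthetic corpus to disk
#'
#' One interchange JSON, one protein PDB and one crystal-ligand SDF per
#' target, plus a `manifest.csv` with the true site centroids (the
#' ground truth used for labelling and evaluation).
#'
#' @param config A [scenario_config()].
#' @param dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest tibble, invisibly.
#' @export
generate_corpus <- function(config, dir, overwrite = FALSE) {
  if (config$n_targets < 1) abort("n_targets must be >= 1")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(paste0("output directory not empty (use overwrite = TRUE): ", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(config$n_targets), function(i) {
    tg <- generate_target(config, i)
    id <- tg$truth$target_id
    ifile <- file.path(dir, paste0(id, ".json"))
    pfile <- file.path(dir, paste0(id, "_protein.pdb"))
    lfile <- file.path(dir, paste0(id, "_ligand.sdf"))
    write_interchange(tg$report, ifile)
    write_structure_pdb(tg$protein, pfile)
    write_structure_sdf(tg$truth$crystal_ligand, lfile)
    tibble::tibble(target_id = id,
                   true_x = tg$truth$true_site[1],
                   true_y = tg$truth$true_site[2],
                   true_z = tg$truth$true_site[3],
                   interchange = basename(ifile), protein = basename(pfile),
                   ligand = basename(lfile))
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Write a structure as an SDF (V2000) file
#'
#' Carries connectivity, unlike PDB output, so symmetry-corrected RMSD
#' can use authored bonds.
#'
#' @param s A `vd_structure` with a bond attribute (bonds perceived
#'   from distances when absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_sdf <- function(s, path) {
  bonds <- attr(s, "bonds")
  if (is.null(bonds)) bonds <- perceive_bonds(s)
  header <- c(attr(s, "mol_name") %||% "molecule", "  voxdock", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      nrow(s), nrow(bonds)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   s$x, s$y, s$z, s$element)
  bond_lines <- sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$order)
  writeLines(c(header, atoms, bond_lines, "M  END", "$$$$"), path)
  invisible(path)
}
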