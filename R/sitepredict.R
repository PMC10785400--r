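#' Rank scored voxels
#'
#' Descending by binding-site score; ties are broken deterministically
#' by greater total pose count, then lexicographic voxel index.
#'
#' @param scored A tibble from [score_voxels()] (columns `ix`, `iy`,
#'   `iz`, `score`, optionally `total_pose_count`).
#' @return The tibble reordered, with a `rank` column prepended.
#' @export
rank_voxels <- function(scored) {
  if (nrow(scored) == 0) abort("no scored voxels to rank")
  if (!"total_pose_count" %in% names(scored)) scored$total_pose_count <- 0
  out <- dplyr::arrange(scored, dplyr::desc(.data$score),
                        dplyr::desc(.data$total_pose_count),
                        .data$ix, .data$iy, .data$iz)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Map a voxel to the nearest detected cavity
#'
#' The predicted binding site is the cavity (from the union of both
#' cavity tools) whose centroid lies nearest the voxel center
#' (Euclidean). Distance ties are broken by smaller cavity rank, then
#' by tool name order (fpocket before p2rank), so the result does not
#' depend on cavity list order. With no cavities at all, the voxel
#' center itself is returned with provenance `"voxel-only"`.
#'
#' @param voxel A one-row tibble with `ix`, `iy`, `iz`, `cx`, `cy`,
#'   `cz` and (if available) `score`/`rank`.
#' @param cavities Cavity tibble (as in a `vd_report`).
#' @return A one-row `vd_site_prediction` tibble: `rank`,
#'   `voxel_score`, voxel index/center, `site_x/y/z`, `provenance`,
#'   `tool`, `cavity_id`, `cavity_distance`.
#' @export
map_to_cavity <- function(voxel, cavities) {
  stopifnot(nrow(voxel) == 1)
  vr <- if ("rank" %in% names(voxel)) voxel$rank else 1L
  vs <- if ("score" %in% names(voxel)) voxel$score else NA_real_
  base <- tibble::tibble(
    rank = vr, voxel_score = vs,
    ix = voxel$ix, iy = voxel$iy, iz = voxel$iz,
    cx = voxel$cx, cy = voxel$cy, cz = voxel$cz
  )
  if (is.null(cavities) || nrow(cavities) == 0) {
    warn("no cavities available; falling back to the voxel center")
    return(structure(dplyr::mutate(base, site_x = .data$cx, site_y = .data$cy,
                                   site_z = .data$cz, provenance = "voxel-only",
                                   tool = NA_character_, cavity_id = NA_integer_,
                                   cavity_distance = 0),
                     class = c("vd_site_prediction", class(base))))
  }
  d <- sqrt((cavities$x - voxel$cx)^2 + (cavities$y - voxel$cy)^2 +
            (cavities$z - voxel$cz)^2)
  ord <- order(d, cavities$cavity_id, match(cavities$tool, cavity_tools()))
  best <- cavities[ord[1], ]
  out <- dplyr::mutate(base, site_x = best$x, site_y = best$y, site_z = best$z,
                       provenance = paste0(best$tool, "#", best$cavity_id),
                       tool = best$tool, cavity_id = best$cavity_id,
                       cavity_distance = d[ord[1]])
  structure(out, class = c("vd_site_prediction", class(out)))
}

#' Top-k distinct binding sites
#'
#' Walks the voxel ranking and reports the first `k` distinct cavities
#' encountered (a cavity is reported once, under the best voxel that
#' mapped to it).
#'
#' @param ranked Output of [rank_voxels()].
#' @param cavities Cavity tibble.
#' @param k Number of sites requested.
#' @return A `vd_site_prediction` tibble with up to `k` rows (fewer,
#'   with a warning, when fewer distinct cavities exist).
#' @export
top_k_sites <- function(ranked, cavities, k = 1) {
  if (k < 1) abort("k must be >= 1")
  seen <- character()
  out <- list()
  for (i in seq_len(nrow(ranked))) {
    pred <- map_to_cavity(ranked[i, ], cavities)
    key <- pred$provenance
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- pred
    if (length(out) == k) break
  }
  res <- dplyr::bind_rows(out)
  res$rank <- seq_len(nrow(res))
  if (nrow(res) < k) {
    warn(sprintf("only %d distinct cavity site(s) available (requested %d)",
                 nrow(res), k))
  }
  structure(res, class = c("vd_site_prediction", class(tibble::tibble())))
}

#' Emit a local-docking box plan around a predicted site
#'
#' A cubic search box (default 15 Angstrom per axis) centred on the
#' predicted site centroid, plus ready-to-run per-program input stubs:
#' an AutoDock Vina config file and generic JSON stubs for the others.
#' The plan documents the fallback order (PLANTS first, then Vina, then
#' GalaxyDock3 by default) but executes nothing; receptor and ligand
#' inputs are expected pre-protonated.
#'
#' @param site A one-row `vd_site_prediction`.
#' @param ligand Optional ligand `vd_structure` (its name is recorded
#'   in the plan).
#' @param extent Box edge in Angstrom (default 15).
#' @param program_order Fallback order (default plants, vina,
#'   galaxydock).
#' @param dir Optional directory in which to write the stub files.
#' @return A `vd_docking_plan` list (`center`, `extent`,
#'   `program_order`, `parameters`, `files`).
#' @export
make_docking_plan <- function(site, ligand = NULL, extent = 15,
                              program_order = c("plants", "vina", "galaxydock"),
                              dir = NULL) {
  if (extent <= 0) abort("extent must be positive")
  if (length(program_order) == 0) abort("program_order must be non-empty")
  unknown <- setdiff(program_order, docking_programs())
  if (length(unknown) > 0) {
    abort(paste0("unknown program(s) in program_order: ",
                 paste(unknown, collapse = ", ")))
  }
  center <- c(x = site$site_x, y = site$site_y, z = site$site_z)
  plan <- structure(
    list(center = center, extent = extent, program_order = program_order,
         parameters = setNames(
           lapply(program_order, function(p) list(defaults = TRUE)),
           program_order),
         ligand = if (is.null(ligand)) NA_character_ else attr(ligand, "mol_name"),
         site_provenance = site$provenance,
         files = character()),
    class = "vd_docking_plan")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    if ("vina" %in% program_order) {
      vina_cfg <- file.path(dir, "vina.conf")
      writeLines(c(
        sprintf("center_x = %.3f", center[1]),
        sprintf("center_y = %.3f", center[2]),
        sprintf("center_z = %.3f", center[3]),
        sprintf("size_x = %g", extent),
        sprintf("size_y = %g", extent),
        sprintf("size_z = %g", extent)
      ), vina_cfg)
      files <- c(files, vina_cfg)
    }
    plan_json <- file.path(dir, "docking_plan.json")
    jsonlite::write_json(
      list(center = unname(center), extent = extent,
           program_order = program_order,
           ligand = plan$ligand, site_provenance = plan$site_provenance,
           note = "inputs expected pre-protonated; executed externally"),
      plan_json, auto_unbox = TRUE, digits = NA)
    files <- c(files, plan_json)
    for (p in setdiff(program_order, "vina")) {
      stub <- file.path(dir, paste0(p, "_stub.json"))
      jsonlite::write_json(list(program = p, center = unname(center),
                                extent = extent, parameters = "defaults"),
                           stub, auto_unbox = TRUE, digits = NA)
      files <- c(files, stub)
    }
    plan$files <- files
  }
  plan
}

#' @export
print.vd_docking_plan <- function(x, ...) {
  cat(sprintf("<vd_docking_plan> %g A box at (%.2f, %.2f, %.2f); order: %s\n",
              x$extent, x$center[1], x$center[2], x$center[3],
              paste(x$program_order, collapse = " -> ")))
  invisible(x)
}

#' Select the final pose from an executed local docking run
#'
#' Takes the poses returned by the external local-docking run (parsed
#' through the adapters) and returns the best-scoring pose — under the
#' program's score polarity — from the first program in the fallback
#' order that produced any poses.
#'
#' @param poses Pose tibble (as in a `vd_report`).
#' @param program_order Fallback order (default plants, vina,
#'   galaxydock).
#' @return A one-row pose tibble.
#' @export
select_final_pose <- function(poses,
                              program_order = c("plants", "vina", "galaxydock")) {
  for (p in program_order) {
    sub <- dplyr::filter(poses, .data$program == p)
    if (nrow(sub) == 0) next
    pol <- score_polarity(p)
    sc <- sub$score
    if (all(is.na(sc))) return(sub[1, ])
    best <- if (pol < 0) which.min(sc) else which.max(sc)
    return(sub[best, ])
  }
  abort("all programs in program_order failed to produce poses")
}
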