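#' Registry of docking programs and cavity tools
#'
#' The pipeline aggregates output from four blind-docking programs
#' (AutoDock Vina, PLANTS, GalaxyDock3, ZDOCK) and two cavity-detection
#' tools (Fpocket, P2Rank). The registry records each component's role,
#' the label used in feature-column names, and the score polarity:
#' `-1` for energy-like scores where lower is better (vina, plants,
#' galaxydock) and `+1` where higher is better (zdock).
#'
#' @return A tibble with columns `program`, `role`, `label`,
#'   `score_polarity`.
#' @export
program_registry <- function() {
  tibble::tribble(
    ~program,      ~role,     ~label,        ~score_polarity,
    "vina",        "docking", "vina",        -1,
    "plants",      "docking", "plants",      -1,
    "galaxydock",  "docking", "galaxydock",  -1,
    "zdock",       "docking", "zdock",        1,
    "fpocket",     "cavity",  "Fpocket",     NA_real_,
    "p2rank",      "cavity",  "P2Rank",      NA_real_
  )
}

docking_programs <- function() {
  reg <- program_registry()
  reg$program[reg$role == "docking"]
}

cavity_tools <- function() {
  reg <- program_registry()
  reg$program[reg$role == "cavity"]
}

program_label <- function(program) {
  reg <- program_registry()
  reg$label[match(program, reg$program)]
}

score_polarity <- function(program) {
  reg <- program_registry()
  reg$score_polarity[match(program, reg$program)]
}

empty_poses <- function() {
  tibble::tibble(program = character(), pose_id = integer(),
                 score = double(), x = double(), y = double(), z = double(),
                 atoms = list())
}

empty_cavities <- function() {
  tibble::tibble(tool = character(), cavity_id = integer(),
                 x = double(), y = double(), z = double(),
                 descriptors = list())
}

#' Assemble a program report for one target
#'
#' A `vd_report` collects every pose and cavity predicted for one target
#' into two tibbles, plus the list of programs that produced no output
#' at all (blind docking has a small but real whole-program failure
#' rate, so failures are tracked explicitly rather than silently
#' yielding empty feature columns).
#'
#' @param target_id Target identifier.
#' @param poses Tibble with columns `program`, `pose_id`, `score`
#'   (NA when the program reported none), `x`, `y`, `z` (mass-centre of
#'   the posed ligand) and a list-column `atoms` of per-pose heavy-atom
#'   tibbles.
#' @param cavities Tibble with columns `tool`, `cavity_id`, `x`, `y`,
#'   `z` and a list-column `descriptors` of named numeric vectors.
#' @param failures Character vector of failed program names.
#' @return A `vd_report` object.
#' @export
new_report <- function(target_id, poses = empty_poses(),
                       cavities = empty_cavities(), failures = character()) {
  poses <- tibble::as_tibble(poses)
  cavities <- tibble::as_tibble(cavities)
  present <- union(unique(poses$program), unique(cavities$tool))
  clash <- intersect(present, failures)
  if (length(clash) > 0) {
    abort(paste0("program(s) listed both with records and as failures: ",
                 paste(clash, collapse = ", ")))
  }
  if (nrow(poses) > 0 && any(poses$pose_id < 1)) abort("pose_id must be >= 1")
  if (nrow(cavities) > 0 && any(cavities$cavity_id < 1)) abort("cavity_id must be >= 1")
  structure(
    list(target_id = target_id, poses = poses, cavities = cavities,
         failures = sort(unique(failures))),
    class = "vd_report"
  )
}

#' @export
print.vd_report <- function(x, ...) {
  cat(sprintf("<vd_report> %s: %d poses (%s), %d cavities (%s), failures: %s\n",
              x$target_id, nrow(x$poses),
              paste(unique(x$poses$program), collapse = ","),
              nrow(x$cavities),
              paste(unique(x$cavities$tool), collapse = ","),
              if (length(x$failures)) paste(x$failures, collapse = ",") else "none"))
  invisible(x)
}

interchange_schema <- "voxdock-interchange/1"

#' Read and write the canonical interchange format
#'
#' All program outputs are normalised into one versioned JSON document
#' per target (`voxdock-interchange/1`). Writing then reading a report
#' reproduces it exactly; cached pose centroids are checked against
#' recomputation from the atoms on read.
#'
#' @param report A `vd_report`.
#' @param path JSON file path.
#' @return `read_interchange()` returns a `vd_report`;
#'   `write_interchange()` returns `path` invisibly.
#' @export
write_interchange <- function(report, path) {
  stopifnot(inherits(report, "vd_report"))
  doc <- list(
    schema = interchange_schema,
    target_id = report$target_id,
    failures = as.list(report$failures),
    poses = purrr::pmap(report$poses, function(program, pose_id, score,
                                               x, y, z, atoms) {
      list(program = program, pose_id = pose_id,
           score = if (is.na(score)) NULL else score,
           centroid = c(x, y, z),
           atoms = list(element = atoms$element, x = atoms$x,
                        y = atoms$y, z = atoms$z))
    }),
    cavities = purrr::pmap(report$cavities, function(tool, cavity_id,
                                                     x, y, z, descriptors) {
      list(tool = tool, cavity_id = cavity_id, centroid = c(x, y, z),
           descriptors = as.list(descriptors))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_interchange
#' @export
read_interchange <- function(path) {
  if (!file.exists(path)) abort(paste0("interchange file not found: ", path))
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, interchange_schema)) {
    abort(paste0("field 'schema': expected '", interchange_schema, "', got '",
                 doc$schema %||% "<missing>", "'"))
  }
  if (is.null(doc$target_id)) abort("field 'target_id' is missing")
  poses <- if (length(doc$poses) == 0) empty_poses() else {
    purrr::map_dfr(doc$poses, function(p) {
      for (f in c("program", "pose_id", "centroid", "atoms")) {
        if (is.null(p[[f]])) abort(paste0("pose field '", f, "' is missing"))
      }
      atoms <- tibble::tibble(
        element = unlist(p$atoms$element),
        x = unlist(p$atoms$x), y = unlist(p$atoms$y), z = unlist(p$atoms$z)
      )
      atoms$mass <- element_mass(atoms$element)
      cen <- unname(unlist(p$centroid))
      chk <- unname(centroid(atoms))
      if (max(abs(chk - cen)) > 1e-6) {
        warn(paste0("pose centroid of ", p$program, " #", p$pose_id,
                    " disagrees with its atoms; recomputed"))
        cen <- chk
      }
      tibble::tibble(program = p$program, pose_id = as.integer(p$pose_id),
                     score = if (is.null(p$score)) NA_real_ else as.numeric(p$score),
                     x = cen[1], y = cen[2], z = cen[3], atoms = list(atoms))
    })
  }
  cavities <- if (length(doc$cavities) == 0) empty_cavities() else {
    purrr::map_dfr(doc$cavities, function(cv) {
      for (f in c("tool", "cavity_id", "centroid")) {
        if (is.null(cv[[f]])) abort(paste0("cavity field '", f, "' is missing"))
      }
      cen <- unlist(cv$centroid)
      tibble::tibble(tool = cv$tool, cavity_id = as.integer(cv$cavity_id),
                     x = cen[1], y = cen[2], z = cen[3],
                     descriptors = list(unlist(cv$descriptors) %||% setNames(numeric(), character())))
    })
  }
  new_report(doc$target_id, poses, cavities,
             unlist(doc$failures) %||% character())
}

# build one PoseRecord row from a posed-ligand structure
pose_row <- function(program, pose_id, score, struct) {
  atoms <- heavy_atoms(struct)
  atoms <- tibble::tibble(element = atoms$element, x = atoms$x, y = atoms$y,
                          z = atoms$z, mass = atoms$mass)
  cen <- unname(centroid(atoms))
  tibble::tibble(program = program, pose_id = as.integer(pose_id),
                 score = score, x = cen[1], y = cen[2], z = cen[3],
                 atoms = list(atoms))
}

#' Parse an fpocket output directory
#'
#' Expects the standard fpocket layout: a `*_info.txt` file with
#' per-pocket `key : value` descriptor blocks and a `pockets/`
#' subdirectory of per-pocket alpha-sphere PQR files
#' (`pocketN_vert.pqr`). The cavity centroid is the mass centre of the
#' pocket's alpha-sphere atoms. Descriptor names are normalised to
#' snake_case (e.g. `number_of_alpha_sphere`, `druggability_score`).
#'
#' @param path Directory path.
#' @return A tibble of cavity records (possibly empty).
#' @export
parse_fpocket_dir <- function(path) {
  if (!dir.exists(path)) abort(paste0("fpocket directory not found: ", path))
  info <- list.files(path, pattern = "_info\\.txt$", full.names = TRUE)
  if (length(info) == 0) abort(paste0("no *_info.txt file in ", path))
  lines <- readLines(info[1], warn = FALSE)
  pocket_starts <- grep("^Pocket\\s+\\d+", lines)
  if (length(pocket_starts) == 0) return(empty_cavities())
  ends <- c(pocket_starts[-1] - 1L, length(lines))
  purrr::map2_dfr(pocket_starts, ends, function(s, e) {
    pid <- as.integer(sub("^Pocket\\s+(\\d+).*", "\\1", lines[s]))
    block <- lines[(s + 1):e]
    kv <- block[grepl(":", block)]
    keys <- normalize_descriptor(sub(":.*$", "", kv))
    vals <- suppressWarnings(as.numeric(trimws(sub("^[^:]*:", "", kv))))
    bad <- is.na(vals)
    if (any(bad)) {
      warn(paste0("fpocket pocket ", pid, ": unparseable descriptor(s) ",
                  paste(keys[bad], collapse = ", "), " marked missing"))
    }
    desc <- setNames(vals[!bad], keys[!bad])
    pqr <- file.path(path, "pockets", sprintf("pocket%d_vert.pqr", pid))
    cen <- if (file.exists(pqr)) fpocket_pqr_centroid(pqr) else {
      warn(paste0("fpocket pocket ", pid, ": PQR file missing, centroid NA"))
      c(NA_real_, NA_real_, NA_real_)
    }
    tibble::tibble(tool = "fpocket", cavity_id = pid,
                   x = cen[1], y = cen[2], z = cen[3],
                   descriptors = list(desc))
  }) |> dplyr::arrange(.data$cavity_id)
}

normalize_descriptor <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  # singular form used in the feature naming convention
  x[x == "number_of_alpha_spheres"] <- "number_of_alpha_sphere"
  x
}

fpocket_pqr_centroid <- function(pqr) {
  lines <- grep("^(ATOM|HETATM)", readLines(pqr, warn = FALSE), value = TRUE)
  if (length(lines) == 0) return(c(NA_real_, NA_real_, NA_real_))
  fields <- strsplit(trimws(lines), "\\s+")
  # PQR: record serial name resname resno x y z charge radius
  xyz <- t(vapply(fields, function(f) as.numeric(f[(length(f) - 4):(length(f) - 2)]),
                  numeric(3)))
  el <- vapply(fields, function(f) substr(f[3], 1, 1), character(1))
  el[!el %in% c("C", "O", "N", "S", "P")] <- "C"
  unname(centroid(tibble::tibble(element = el, x = xyz[, 1], y = xyz[, 2],
                                 z = xyz[, 3], mass = element_mass(el))))
}

#' Parse a P2Rank predictions CSV
#'
#' Expects the standard P2Rank `*_predictions.csv` with columns `rank`,
#' `center_x`, `center_y`, `center_z` and typically `score` and
#' `probability`. All additional numeric columns are kept as cavity
#' descriptors.
#'
#' @param path CSV file path.
#' @return A tibble of cavity records ordered by rank (possibly empty).
#' @export
parse_p2rank_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("p2rank CSV not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, trim_ws = TRUE,
                        name_repair = "minimal")
  names(df) <- trimws(names(df))
  need <- c("rank", "center_x", "center_y", "center_z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("p2rank CSV is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(empty_cavities())
  df <- dplyr::arrange(df, .data$rank)
  desc_cols <- setdiff(names(df), c(need, "name"))
  purrr::pmap_dfr(list(seq_len(nrow(df))), function(i) {
    row <- df[i, ]
    desc <- suppressWarnings(
      vapply(desc_cols, function(cl) as.numeric(row[[cl]]), numeric(1)))
    tibble::tibble(tool = "p2rank", cavity_id = as.integer(row$rank),
                   x = row$center_x, y = row$center_y, z = row$center_z,
                   descriptors = list(desc[!is.na(desc)]))
  })
}

#' Parse AutoDock Vina multi-MODEL PDBQT output
#'
#' One pose per `MODEL` block; the score is the first number on the
#' `REMARK VINA RESULT` line (marked missing when the remark is absent).
#' Hydrogens are excluded from the pose atoms.
#'
#' @param path PDBQT file path.
#' @return A tibble of pose records (empty when no MODEL records).
#' @export
parse_vina_pdbqt <- function(path) {
  if (!file.exists(path)) abort(paste0("PDBQT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) return(empty_poses())
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  purrr::map2_dfr(seq_along(starts), starts, function(k, s) {
    block <- lines[s:ends[k]]
    res <- grep("^REMARK VINA RESULT", block, value = TRUE)
    score <- if (length(res) > 0) {
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:?", "", res[1])),
                          "\\s+")[[1]][1])
    } else NA_real_
    at <- grep("^(ATOM|HETATM)", block, value = TRUE)
    elem <- pdbqt_element(at)
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54)))
    keep <- !elem %in% c("H", "D")
    if (!any(keep)) abort(paste0("model ", k, " in ", path, " has no heavy atoms"))
    struct <- as_structure(
      tibble::tibble(element = elem[keep], x = xyz[keep, 1],
                     y = xyz[keep, 2], z = xyz[keep, 3]),
      name = paste0("vina_pose_", k), kind = "ligand")
    pose_row("vina", k, score, struct)
  })
}

# AutoDock atom types -> element (OA->O, NA->N, HD->H, A (aromatic C) -> C)
pdbqt_element <- function(atom_lines) {
  type <- trimws(substr(atom_lines, 78, 80))
  blank <- type == ""
  type[blank] <- trimws(substr(atom_lines[blank], 13, 14))
  map <- c(A = "C", OA = "O", NA. = "N", SA = "S", HD = "H", HS = "H",
           CL = "Cl", BR = "Br", FE = "Fe", ZN = "Zn", MG = "Mg", MN = "Mn")
  key <- ifelse(toupper(type) == "NA", "NA.", toupper(type))
  mapped <- map[key]
  out <- ifelse(is.na(mapped), normalize_element(type), mapped)
  unname(out)
}

#' Parse a multi-entry pose file for any docking program
#'
#' Convenience reader for PLANTS/GalaxyDock3/ZDOCK poses pre-converted
#' to a multi-entry MOL2, SDF or multi-MODEL PDB file. ZDOCK's native
#' transformation output is not decoded; poses must arrive as
#' coordinates. Scores are attached by entry index from an optional
#' table; entries beyond the table get a missing score (later mean
#' imputed).
#'
#' @param path Molecule file path.
#' @param program Registered docking program name.
#' @param format `"mol2"`, `"pdb"` or `"sdf"`.
#' @param scores Optional numeric vector or data frame with a `score`
#'   column, aligned to entry order.
#' @return A tibble of pose records in file order (empty when the file
#'   holds no entries).
#' @export
parse_generic_poses <- function(path, program, format = c("mol2", "pdb", "sdf"),
                                scores = NULL) {
  format <- match.arg(format)
  if (!program %in% docking_programs()) {
    abort(paste0("unknown docking program: ", program))
  }
  if (!file.exists(path)) abort(paste0("pose file not found: ", path))
  if (is.data.frame(scores)) scores <- scores$score
  chunks <- split_entries(readLines(path, warn = FALSE), format)
  if (length(chunks) == 0) return(empty_poses())
  purrr::imap_dfr(chunks, function(chunk, k) {
    tmp <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(tmp))
    writeLines(chunk, tmp)
    struct <- read_structure(tmp, format = format, kind = "ligand")
    sc <- if (!is.null(scores) && k <= length(scores)) scores[k] else NA_real_
    pose_row(program, k, sc, heavy_atoms(struct))
  })
}

split_entries <- function(lines, format) {
  if (format == "sdf") {
    idx <- grep("^\\$\\$\\$\\$", lines)
    if (length(idx) == 0) idx <- length(lines)
    starts <- c(1L, head(idx, -1) + 1L)
    chunks <- purrr::map2(starts, idx, function(s, e) c(lines[s:e]))
    purrr::keep(chunks, ~ any(grepl("V2000", .x)))
  } else if (format == "mol2") {
    idx <- grep("^@<TRIPOS>MOLECULE", lines)
    if (length(idx) == 0) return(list())
    ends <- c(idx[-1] - 1L, length(lines))
    purrr::map2(idx, ends, ~ lines[.x:.y])
  } else {
    idx <- grep("^MODEL", lines)
    if (length(idx) == 0) {
      if (any(grepl("^(ATOM|HETATM)", lines))) return(list(lines))
      return(list())
    }
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(idx)) ends <- c(ends, length(lines))
    purrr::map2(idx, ends[seq_along(idx)], ~ lines[.x:.y])
  }
}
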