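#' Read and write force-distance curves
#'
#' Plain-text TSV dialect: `#`-prefixed `key: value` metadata header
#' lines (at minimum `retraction_speed`, `spring_constant`, and a
#' `n_rows` row-count checksum used to reject truncated files),
#' followed by a header row and two columns `distance_nm`, `force_pN`.
#' Unix and Windows line endings are both accepted. The round trip is
#' lossless to full double precision.
#'
#' @param path File path.
#' @param curve A data frame with `distance_nm` and `force_pN`.
#' @param retraction_speed,spring_constant Metadata (nm/s, pN/nm).
#' @param id Optional curve label stored in the header.
#' @return `read_fd_curve()`: a list with `curve` (tibble),
#'   `retraction_speed`, `spring_constant`, `id`. `write_fd_curve()`:
#'   the path, invisibly.
#' @export
write_fd_curve <- function(curve, path, retraction_speed = 500,
                           spring_constant = 25, id = "curve") {
  stopifnot(all(c("distance_nm", "force_pN") %in% names(curve)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# id: %s", id),
    sprintf("# retraction_speed: %.17g", retraction_speed),
    sprintf("# spring_constant: %.17g", spring_constant),
    sprintf("# n_rows: %d", nrow(curve)),
    "distance_nm\tforce_pN"), con)
  writeLines(sprintf("%.17g\t%.17g", curve$distance_nm, curve$force_pN), con)
  invisible(path)
}

parse_meta_header <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$",
                           meta_lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  out
}

#' @rdname write_fd_curve
#' @export
read_fd_curve <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  meta <- parse_meta_header(lines)
  for (key in c("retraction_speed", "spring_constant", "n_rows")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("curve file %s is missing metadata key '%s'.",
                    path, key),
            class = "smc_format_error")
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  header <- strsplit(body[1], "\t")[[1]]
  if (!identical(header, c("distance_nm", "force_pN"))) {
    abort("curve file must have columns distance_nm, force_pN.",
          class = "smc_format_error")
  }
  rows <- strsplit(body[-1], "\t")
  n_expected <- as.integer(meta$n_rows)
  if (length(rows) != n_expected) {
    abort(sprintf("curve file %s is truncated: %d rows, header says %d.",
                  path, length(rows), n_expected),
          class = "smc_format_error")
  }
  vals <- matrix(as.numeric(unlist(rows)), ncol = 2, byrow = TRUE)
  list(curve = tibble(distance_nm = vals[, 1], force_pN = vals[, 2]),
       retraction_speed = as.numeric(meta$retraction_speed),
       spring_constant = as.numeric(meta$spring_constant),
       id = meta$id %||% NA_character_)
}

#' Read and write AFM topographs
#'
#' A topograph is stored as a plain whitespace-separated matrix of
#' heights in nm plus a JSON sidecar `<path>.json` holding at least
#' `pixel_nm` (and `n_rows`/`n_cols` checksums). NaN cells are
#' rejected with their position.
#'
#' @param topo A `topograph` object.
#' @param path Matrix file path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `read_topograph()`: a `topograph`; `write_topograph()`: the
#'   path, invisibly.
#' @export
write_topograph <- function(topo, path) {
  stopifnot(inherits(topo, "topograph"))
  utils::write.table(topo$heights, path, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pixel_nm = topo$pixel_nm, n_rows = nrow(topo$heights),
         n_cols = ncol(topo$heights), id = topo$id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing JSON sidecar %s (needs pixel_nm).", sidecar),
          class = "smc_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_nm) || meta$pixel_nm <= 0) {
    abort("sidecar must provide pixel_nm > 0.", class = "smc_format_error")
  }
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!is.null(meta$n_rows) &&
      (nrow(m) != meta$n_rows || ncol(m) != meta$n_cols)) {
    abort(sprintf("topograph %s is truncated: %d x %d, sidecar says %d x %d.",
                  path, nrow(m), ncol(m), meta$n_rows, meta$n_cols),
          class = "smc_format_error")
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-finite height at row %d, col %d.",
                  bad[1, 1], bad[1, 2]),
          class = "smc_format_error")
  }
  structure(list(heights = m, pixel_nm = meta$pixel_nm,
                 features = NULL, id = meta$id %||% basename(path)),
            class = "topograph")
}

#' Read and write coarse-grained models
#'
#' The bead geometry is stored as a Calpha-only PDB (via bio3d) and
#' the topology (chains, bonds, contacts, pulling groups) as a JSON
#' sidecar `<path>.json`.
#'
#' @param model A `cg_model` object.
#' @param path PDB file path; the sidecar goes to `paste0(path,
#'   ".json")`.
#' @return `read_cg_model()`: a `cg_model`; `write_cg_model()`: the
#'   path, invisibly.
#' @export
write_cg_model <- function(model, path) {
  stopifnot(inherits(model, "cg_model"))
  n <- nrow(model$coords)
  aa3 <- c(C = "CYS", H = "HIS", Q = "GLN", K = "LYS", L = "LEU",
           V = "VAL", F = "PHE", A = "ALA", E = "GLU", D = "ASP",
           Y = "TYR", N = "ASN", G = "GLY")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model$coords)) * 10,  # nm -> Angstrom
    resno = seq_len(n), resid = aa3[model$residue],
    chain = LETTERS[model$chain], elety = rep("CA", n))
  jsonlite::write_json(
    list(kind = model$kind, chain = model$chain,
         residue = model$residue,
         bonds = as.data.frame(model$bonds),
         contacts = as.data.frame(model$contacts),
         pulling_groups = model$pulling_groups,
         sigma_rep = model$sigma_rep),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cg_model
#' @export
read_cg_model <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing JSON sidecar %s (topology).", sidecar),
          class = "smc_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pdb <- bio3d::read.pdb(path)
  coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
  structure(list(coords = coords, chain = as.integer(meta$chain),
                 residue = meta$residue,
                 bonds = as_tibble(meta$bonds),
                 contacts = as_tibble(meta$contacts),
                 pulling_groups = as.integer(meta$pulling_groups),
                 sigma_rep = meta$sigma_rep, kind = meta$kind),
            class = "cg_model")
}

#' Read and write dihedral trajectories
#'
#' Wide TSV: `#`-prefixed metadata (`n_residues`, `n_rows` checksum),
#' then one column per angle named `phi_<r>` / `psi_<r>` and one row
#' per frame, degrees.
#'
#' @param traj A `dihedral_traj` object.
#' @param path File path.
#' @return `read_dihedral_traj()`: a `dihedral_traj` (without state
#'   labels); `write_dihedral_traj()`: the path, invisibly.
#' @export
write_dihedral_traj <- function(traj, path) {
  stopifnot(inherits(traj, "dihedral_traj"))
  n_res <- max(traj$labels$residue)
  cols <- paste0(traj$labels$angle, "_", traj$labels$residue)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_residues: %d", n_res),
               sprintf("# n_rows: %d", nrow(traj$angles)),
               paste(cols, collapse = "\t")), con)
  utils::write.table(traj$angles, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_traj
#' @export
read_dihedral_traj <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  meta <- parse_meta_header(lines)
  if (is.null(meta$n_residues)) {
    abort("dihedral file is missing 'n_residues' metadata.",
          class = "smc_format_error")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  rows <- strsplit(body[-1], "\t")
  if (!is.null(meta$n_rows) && length(rows) != as.integer(meta$n_rows)) {
    abort(sprintf("dihedral file truncated: %d rows, header says %s.",
                  length(rows), meta$n_rows),
          class = "smc_format_error")
  }
  ang <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
  parts <- regmatches(cols, regexec("^(phi|psi)_([0-9]+)$", cols))
  labels <- tibble(residue = as.integer(vapply(parts, `[`, "", 3)),
                   angle = vapply(parts, `[`, "", 2))
  n_res <- as.integer(meta$n_residues)
  structure(list(angles = ang, labels = labels,
                 terminal_mask = labels$residue %in% c(1L, n_res),
                 state = NULL),
            class = "dihedral_traj")
}
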