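# File formats: multi-frame XYZ trajectories, topology JSON, contour CSV,
# tidy CSV/JSON result writers, PDB input (C-alpha extraction via bio3d),
# and the run manifest. Coordinates are Angstrom internally; the fibril
# metrology module works in nanometres (converted at its boundary).

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text XYZ; the comment line of each frame carries time, replica and
#' seed, so a fixed seed gives byte-identical output.
#'
#' @param trajectory a `dmd_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  b <- trajectory$topology$beads
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[k]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("time=%.6f replica=%s seed=%s box=%.4f",
                       trajectory$times[k],
                       trajectory$replica, trajectory$seed,
                       trajectory$box), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", b$residue,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file written by [write_trajectory_xyz()].
#' @param topology optional matching topology to attach.
#' @return A `dmd_trajectory` (without energies).
#' @export
read_trajectory_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); box <- NA_real_
  k <- 1L
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    meta <- lines[k + 1L]
    tm <- as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", meta))
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", meta))
    body <- lines[(k + 2L):(k + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    fr <- matrix(as.numeric(parts[, 2:4]), n, 3)
    frames <- c(frames, list(fr))
    times <- c(times, tm)
    k <- k + 2L + n
  }
  structure(list(times = times, frames = frames,
                 e_kin = rep(NA_real_, length(frames)),
                 e_pot = rep(NA_real_, length(frames)),
                 t_final = max(times), n_events = NA_real_,
                 counts = NULL, seed = NA_integer_, replica = NA_integer_,
                 box = box, temperature = NA_real_,
                 topology = topology, interactions = NULL),
            class = "dmd_trajectory")
}

#' Serialize a topology to JSON
#'
#' @param topology a `dmd_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(list(beads = topology$beads,
                            bonds = topology$bonds,
                            x = topology$x),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path file written by [write_topology_json()].
#' @return A `dmd_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beads <- as.data.frame(obj$beads, stringsAsFactors = FALSE)
  bonds <- as.data.frame(obj$bonds)
  if (nrow(bonds) == 0) bonds <- .empty_bonds()
  .new_topology(beads, bonds, matrix(as.numeric(obj$x), nrow(beads), 3))
}

#' Read a structure file into a topology
#'
#' PDB files are reduced to one bead per residue at the C-alpha position
#' (per chain, ordered by residue number and insertion code, 1-based
#' numbering preserved from the source); topology JSON round-trips the
#' package's own format.
#'
#' @param path input file.
#' @param format `"pdb"` or `"json"` (guessed from the extension by
#'   default).
#' @param params residue parameter table for PDB input.
#' @return A `dmd_topology` with coordinates.
#' @export
read_structure <- function(path, format = NULL,
                           params = residue_params()) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "pdb"
  }
  format <- match.arg(format, c("pdb", "json"))
  if (format == "json") return(read_topology_json(path))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms in ", path, call. = FALSE)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  ord <- order(at$chain, at$resno, ins)
  at <- at[ord, , drop = FALSE]
  three <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  code <- three[at$resid]
  if (any(is.na(code))) {
    stop("unknown residue '", at$resid[which(is.na(code))[1]],
         "' at PDB line for residue ", at$resno[which(is.na(code))[1]],
         call. = FALSE)
  }
  n <- nrow(at)
  beads <- .bead_frame(n)
  beads$mass <- params[code, "mass"]
  beads$radius <- params[code, "radius"]
  beads$charge <- params[code, "charge"]
  beads$hydrophobicity <- params[code, "hydrophobicity"]
  beads$residue <- unname(code)
  beads$resindex <- at$resno
  beads$chain <- as.integer(factor(at$chain))
  beads$mol <- 1L
  beads$kind <- "protein"
  beads$mobile <- TRUE
  beads$exposed <- TRUE
  .new_topology(beads, .empty_bonds(),
                cbind(at$x, at$y, at$z))
}

#' Write contours as tidy CSV
#'
#' Columns `contour`, `x`, `y` and (when present) `width`; all in nm.
#'
#' @param contours contour list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  cl <- .as_contour_list(contours)
  rows <- lapply(seq_along(cl), function(i) {
    ct <- cl[[i]]
    df <- data.frame(contour = i, x = ct$points[, 1], y = ct$points[, 2])
    if (!is.null(ct$width)) df$width <- ct$width
    df
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read contours from tidy CSV
#'
#' @param path CSV with columns `contour`, `x`, `y` and optionally
#'   `width` (nm).
#' @return list of contours.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$contour), function(d) {
    out <- list(points = cbind(d$x, d$y))
    if (!is.null(d$width)) out$width <- d$width
    out
  })
}

#' Write a cluster set as JSON
#' @param cluster_set a `dmd_cluster_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(cluster_set, path) {
  jsonlite::write_json(list(mols = cluster_set$mols,
                            kinds = cluster_set$kinds,
                            membership = cluster_set$membership),
                       path, digits = NA)
  invisible(path)
}

#' Read a cluster set from JSON
#' @param path file written by [write_clusters_json()].
#' @return A `dmd_cluster_set` (membership and composition).
#' @export
read_clusters_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  membership <- as.integer(obj$membership)
  comp <- data.frame(
    cluster = sort(unique(membership)),
    size = as.integer(table(membership)),
    n_peptides = as.integer(tapply(obj$kinds == "peptide", membership, sum)),
    n_proteins = as.integer(tapply(obj$kinds == "protein", membership, sum)))
  structure(list(mols = as.integer(obj$mols), kinds = obj$kinds,
                 membership = membership, composition = comp),
            class = "dmd_cluster_set")
}

#' Run manifest for reproducibility
#'
#' Records the protocol parameters, seeds, package version and file
#' hashes needed to re-run a result.
#'
#' @param protocol a `dmd_protocol` (or parameter list).
#' @param seed base seed.
#' @param files character vector of output paths to hash.
#' @return list (manifest content).
#' @export
run_manifest <- function(protocol, seed, files = character(0)) {
  hashes <- vapply(files, function(f) {
    if (!file.exists(f)) return(NA_character_)
    as.character(tools::md5sum(f))
  }, character(1))
  list(protocol = unclass(protocol), seed = seed,
       package_version = as.character(utils::packageVersion("cgdmd")),
       r_version = R.version.string,
       created = format(Sys.time(), tz = "UTC"),
       files = as.list(hashes))
}

#' Write analysis results and manifest to a directory
#'
#' Data frames become CSV, other objects JSON; the manifest is always
#' written as `manifest.json`.
#'
#' @param objects named list of result objects.
#' @param out_dir output directory (created if needed).
#' @param manifest a [run_manifest()] list.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(objects, out_dir, manifest = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(obj, p, row.names = FALSE)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, digits = NA, auto_unbox = TRUE,
                           force = TRUE)
    }
    paths <- c(paths, p)
  }
  if (!is.null(manifest)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, digits = NA, auto_unbox = TRUE,
                         force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a peptide sequence from a string or FASTA file
#'
#' Accepts a plain 1-letter amino-acid string, a path to a single-record
#' FASTA file, or FASTA-formatted text (leading `>` header). FASTA input
#' is parsed with Biostrings.
#'
#' @param x sequence string, FASTA text, or FASTA file path.
#' @return Upper-case amino-acid string.
#' @export
read_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_file <- file.exists(x) && !dir.exists(x)
  if (is_file || startsWith(trimws(x), ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    if (!is_file) {
      f <- tempfile(fileext = ".fasta")
      writeLines(x, f)
      on.exit(unlink(f))
      x <- f
    }
    set <- Biostrings::readAAStringSet(x)
    if (length(set) != 1L) {
      stop("expected a single-record FASTA, found ", length(set),
           " records", call. = FALSE)
    }
    return(toupper(as.character(set[[1]])))
  }
  toupper(x)
}
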