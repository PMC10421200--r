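# Structure and trajectory I/O.
#
# XYZ: extended comment line carrying box vectors and periodicity, e.g.
#   box="21.64 22.95 15.31" periodic="TTF" time_ps="0.0"
# GRO: native nm units, 1-based numbering, one residue per structure.
# PDB: delegated to bio3d (CRYST1 for the box).
# Hills / CV / PMF files: whitespace-separated tables with a
# "#! FIELDS ..." header line, dialect-compatible with the common
# enhanced-sampling hills format.

#' Write a structure (or trajectory frames) as (extended) XYZ
#'
#' @param x A `nanostructure`, or a `trajectory` for multi-frame output.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_xyz <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(x, "trajectory")) {
    for (k in seq_along(x$frames))
      .write_xyz_frame(con, x$species, x$frames[[k]], x$box, x$periodic,
                       x$times[k])
  } else {
    .write_xyz_frame(con, x$species, x$xyz, x$box, x$periodic, NA)
  }
  invisible(file)
}

.write_xyz_frame <- function(con, species, xyz, box, periodic, time_ps) {
  writeLines(as.character(nrow(xyz)), con)
  cmt <- sprintf('box="%.6f %.6f %.6f" periodic="%s"',
                 box[1], box[2], box[3],
                 paste(ifelse(periodic, "T", "F"), collapse = ""))
  if (!is.na(time_ps)) cmt <- paste0(cmt, sprintf(' time_ps="%.6f"', time_ps))
  writeLines(cmt, con)
  writeLines(sprintf("%-4s %14.8f %14.8f %14.8f",
                     species, xyz[, 1], xyz[, 2], xyz[, 3]), con)
}

#' Read an (extended) XYZ file
#'
#' Single-frame files return a `nanostructure`; multi-frame files return a
#' `trajectory`.
#'
#' @param file Path to an XYZ file written by [write_xyz()] (or plain XYZ;
#'   missing box metadata yields a zero box and no periodicity).
#' @return A `nanostructure` or `trajectory`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); times <- numeric(0)
  species <- NULL; box <- c(0, 0, 0); periodic <- c(FALSE, FALSE, FALSE)
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    cmt <- lines[i + 1]
    bm <- regmatches(cmt, regexec('box="([^"]+)"', cmt))[[1]]
    if (length(bm) == 2) box <- as.numeric(strsplit(trimws(bm[2]), "\\s+")[[1]])
    pm <- regmatches(cmt, regexec('periodic="([TF]{3})"', cmt))[[1]]
    if (length(pm) == 2) periodic <- strsplit(pm[2], "")[[1]] == "T"
    tm <- regmatches(cmt, regexec('time_ps="([^"]+)"', cmt))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    rec <- do.call(rbind, strsplit(trimws(lines[i + 2:(n + 1)]), "\\s+"))
    species <- rec[, 1]
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(rec[, 2:4]), ncol = 3)
    i <- i + n + 2
  }
  if (length(frames) == 1)
    nanostructure(species, frames[[1]], box, periodic)
  else
    trajectory(frames, times, species = species, box = box, periodic = periodic)
}

#' Write a structure in GRO format (nm units)
#' @param x A `nanostructure`.
#' @param file Output path.
#' @param title Title line.
#' @return Invisibly, `file`.
#' @export
write_gro <- function(x, file, title = "nanosorb structure") {
  n <- n_atoms(x)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     1L, "MOL", substr(x$species, 1, 5), seq_len(n) %% 100000L,
                     x$xyz[, 1] / 10, x$xyz[, 2] / 10, x$xyz[, 3] / 10),
             sprintf("%10.5f%10.5f%10.5f",
                     x$box[1] / 10, x$box[2] / 10, x$box[3] / 10))
  writeLines(lines, file)
  invisible(file)
}

#' Read a GRO file
#' @param file Path.
#' @return A `nanostructure` (positions converted from nm to Angstrom).
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  at <- lines[2 + seq_len(n)]
  species <- trimws(substr(at, 11, 15))
  xyz <- cbind(as.numeric(substr(at, 21, 28)),
               as.numeric(substr(at, 29, 36)),
               as.numeric(substr(at, 37, 44))) * 10
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3] * 10
  nanostructure(species, xyz, box, periodic = c(TRUE, TRUE, TRUE))
}

#' Write a structure in PDB format
#'
#' Uses bio3d; the box goes into the CRYST1 record.
#'
#' @param x A `nanostructure`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pdb <- function(x, file) {
  n <- n_atoms(x)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(x$xyz)),
                   type = rep("ATOM", n),
                   eleno = seq_len(n),
                   elety = x$species,
                   resno = rep(1L, n),
                   resid = rep("MOL", n),
                   chain = rep("A", n),
                   elesy = substr(x$species, 1, 2))
  # bio3d only writes CRYST1 from a pdb object; prepend one ourselves
  lines <- readLines(file)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   x$box[1], x$box[2], x$box[3], 90, 90, 90)
  writeLines(c(cryst, lines), file)
  invisible(file)
}

#' Read a PDB file into a nanostructure
#' @param file Path.
#' @return A `nanostructure` (CRYST1 box if present; assumed periodic).
#' @export
read_pdb_structure <- function(file) {
  pdb <- bio3d::read.pdb(file)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  species <- trimws(pdb$atom$elety)
  box <- c(0, 0, 0); per <- c(FALSE, FALSE, FALSE)
  lines <- readLines(file, n = 20)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) >= 1) {
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
    per <- box > 0
  }
  nanostructure(species, xyz, box, per)
}

#' Export bond/angle topology as a plain-text table
#' @param structure A `nanostructure` with derived topology.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_topology <- function(structure, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# nanosorb topology: %d atoms", n_atoms(structure)), con)
  writeLines("[ bonds ]", con)
  if (nrow(structure$bonds) > 0)
    writeLines(sprintf("%d %d", structure$bonds[, 1], structure$bonds[, 2]), con)
  writeLines("[ angles ]", con)
  if (nrow(structure$angles) > 0)
    writeLines(sprintf("%d %d %d", structure$angles[, 1],
                       structure$angles[, 2], structure$angles[, 3]), con)
  invisible(file)
}

#' Read a topology table written by [write_topology()]
#' @param file Path.
#' @return List with integer matrices `bonds` and `angles`.
#' @export
read_topology <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines)]
  ib <- which(lines == "[ bonds ]")
  ia <- which(lines == "[ angles ]")
  parse_block <- function(lns, ncol) {
    lns <- lns[nzchar(trimws(lns))]
    if (!length(lns)) return(matrix(integer(0), 0, ncol))
    do.call(rbind, lapply(strsplit(trimws(lns), "\\s+"), as.integer))
  }
  list(bonds = parse_block(lines[seq(ib + 1, ia - 1)], 2),
       angles = parse_block(lines[seq(ia + 1, length(lines))], 3))
}

#' Write a hills file
#'
#' Whitespace-separated records `(time, s, sigma, height)` under a
#' `#! FIELDS` header, compatible with the common enhanced-sampling hills
#' dialect.  Times in ps, `s` and `sigma` in nm, heights in kJ/mol.
#'
#' @param hills data.frame with columns time, s, sigma, height.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_hills <- function(hills, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time s sigma_s height", con)
  if (nrow(hills) > 0)
    writeLines(sprintf("%.6f %.9f %.9f %.9f",
                       hills$time, hills$s, hills$sigma, hills$height), con)
  invisible(file)
}

#' Read a hills file
#' @param file Path.
#' @return data.frame with columns time, s, sigma, height.
#' @export
read_hills <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(time = numeric(0), s = numeric(0),
                      sigma = numeric(0), height = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(time = m[, 1], s = m[, 2], sigma = m[, 3], height = m[, 4])
}

#' Write a CV time-series file
#' @param cv data.frame with columns time, s, force, bias.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_cv_series <- function(cv, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time s force bias", con)
  writeLines(sprintf("%.6f %.9f %.9f %.9f", cv$time, cv$s, cv$force, cv$bias),
             con)
  invisible(file)
}

#' Read a CV time-series file
#' @param file Path.
#' @return data.frame with columns time, s, force, bias.
#' @export
read_cv_series <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(time = m[, 1], s = m[, 2], force = m[, 3], bias = m[, 4])
}

#' Write a PMF curve as TSV with a metadata header
#' @param pmf A [pmf_curve()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pmf <- function(pmf, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K\t%.6f", pmf$temperature), con)
  writeLines(sprintf("# reference\t%s", pmf$reference), con)
  writeLines("# s_nm\tW_kJmol", con)
  writeLines(sprintf("%.9f\t%.9f", pmf$s, pmf$W), con)
  invisible(file)
}

#' Read a PMF file written by [write_pmf()]
#' @param file Path.
#' @return A [pmf_curve()].
#' @export
read_pmf <- function(file) {
  lines <- readLines(file)
  hdr <- lines[grepl("^#", lines)]
  dat <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  temp <- 300
  ref <- "bulk-zero"
  tl <- grep("temperature_K", hdr, value = TRUE)
  if (length(tl)) temp <- as.numeric(strsplit(tl, "\t")[[1]][2])
  rl <- grep("reference", hdr, value = TRUE)
  if (length(rl)) ref <- strsplit(rl, "\t")[[1]][2]
  m <- do.call(rbind, lapply(strsplit(dat, "\t"), as.numeric))
  pmf_curve(m[, 1], m[, 2], temperature = temp, reference = ref)
}
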