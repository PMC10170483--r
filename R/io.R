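# Readers and writers for the standard text formats: LAMMPS data files
# (full style), LAMMPS dump trajectories, multi-frame XYZ, CSV tables.
#
# Convention: LAMMPS data and dump files use Angstrom (the native
# convention of the simulations this model targets); everything else in
# the package is nm. Conversions happen on read/write and are noted in
# the file headers.

#' Write a system as a LAMMPS data file (full atom style)
#'
#' Sections: header counts, box bounds, Masses, Atoms (id mol type q x y
#' z), Bonds, Angles. Coordinates are written in Angstrom. Bead-type,
#' bond-type and angle-type maps plus rigid-group membership are embedded
#' as structured comments so that [read_lammps_data] can reconstruct the
#' full topology.
#'
#' @param system A `cg_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(system, path) {
  types <- sort(unique(system$type))
  bkeys <- if (nrow(system$bonds))
    sort(unique(mapply(pair_key, system$bonds$type_i, system$bonds$type_j)))
  else character()
  akeys <- if (nrow(system$angles))
    sort(unique(mapply(angle_key, system$angles$type_i, system$angles$type_j,
                       system$angles$type_k)))
  else character()
  n <- length(system$type)
  out <- c("cgnp LAMMPS data file (units: Angstrom, charges in e)",
           "",
           sprintf("%d atoms", n),
           sprintf("%d bonds", nrow(system$bonds)),
           sprintf("%d angles", nrow(system$angles)),
           sprintf("%d atom types", length(types)),
           if (length(bkeys)) sprintf("%d bond types", length(bkeys)),
           if (length(akeys)) sprintf("%d angle types", length(akeys)),
           "",
           sprintf("0.0 %.8f xlo xhi", system$box[1] * 10),
           sprintf("0.0 %.8f ylo yhi", system$box[2] * 10),
           sprintf("0.0 %.8f zlo zhi", system$box[3] * 10),
           "",
           paste("# typemap", paste(types, collapse = " ")),
           if (length(bkeys)) paste("# bondmap", paste(bkeys, collapse = " ")),
           if (length(akeys)) paste("# anglemap", paste(akeys, collapse = " ")))
  for (g in seq_along(system$rigid_groups))
    out <- c(out, paste("# rigid", paste(system$rigid_groups[[g]],
                                         collapse = " ")))
  # per-type mass: first occurrence wins (types have fixed masses)
  out <- c(out, "", "Masses", "")
  for (t in seq_along(types)) {
    m <- system$mass[match(types[t], system$type)]
    out <- c(out, sprintf("%d %.6f  # %s", t, m, types[t]))
  }
  out <- c(out, "", "Atoms # full", "")
  ti <- match(system$type, types)
  mol <- if (length(system$molecule)) system$molecule else rep(1L, n)
  out <- c(out, sprintf("%d %d %d %.6f %.8f %.8f %.8f",
                        seq_len(n), mol, ti, system$charge,
                        system$positions[, 1] * 10,
                        system$positions[, 2] * 10,
                        system$positions[, 3] * 10))
  if (nrow(system$bonds)) {
    bt <- match(mapply(pair_key, system$bonds$type_i, system$bonds$type_j),
                bkeys)
    out <- c(out, "", "Bonds", "",
             sprintf("%d %d %d %d", seq_len(nrow(system$bonds)), bt,
                     system$bonds$i, system$bonds$j))
  }
  if (nrow(system$angles)) {
    at <- match(mapply(angle_key, system$angles$type_i, system$angles$type_j,
                       system$angles$type_k), akeys)
    out <- c(out, "", "Angles", "",
             sprintf("%d %d %d %d %d", seq_len(nrow(system$angles)), at,
                     system$angles$i, system$angles$j, system$angles$k))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a LAMMPS data file written by [write_lammps_data]
#'
#' @param path File path.
#' @param ff Force field used to restore per-bead masses/charges when the
#'   type maps are present. Default [default_forcefield()].
#' @return A `cg_system` (coordinates converted to nm).
#' @export
read_lammps_data <- function(path, ff = ff_default_cached()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5) stop("malformed LAMMPS data file: too short")
  grab_count <- function(pat) {
    hit <- grep(pat, lines, value = TRUE)
    if (!length(hit)) return(0L)
    as.integer(strsplit(trimws(hit[1]), "[[:space:]]+")[[1]][1])
  }
  n <- grab_count(" atoms$")
  nb <- grab_count(" bonds$")
  na_ <- grab_count(" angles$")
  if (is.na(n) || n <= 0) stop("malformed LAMMPS data file: no atom count")
  box_line <- function(pat) {
    hit <- grep(pat, lines, value = TRUE)
    if (!length(hit)) stop("malformed LAMMPS data file: missing box bounds")
    v <- as.numeric(strsplit(trimws(hit[1]), "[[:space:]]+")[[1]][1:2])
    (v[2] - v[1]) / 10
  }
  box <- c(box_line("xlo xhi"), box_line("ylo yhi"), box_line("zlo zhi"))
  map_of <- function(tag) {
    hit <- grep(paste0("^# ", tag, " "), lines, value = TRUE)
    if (!length(hit)) return(character())
    strsplit(sub(paste0("^# ", tag, " "), "", hit[1]), "[[:space:]]+")[[1]]
  }
  typemap <- map_of("typemap")
  bondmap <- map_of("bondmap")
  anglemap <- map_of("anglemap")
  rigid_lines <- grep("^# rigid ", lines, value = TRUE)
  rigid_groups <- lapply(rigid_lines, function(l)
    as.integer(strsplit(sub("^# rigid ", "", l), "[[:space:]]+")[[1]]))
  section <- function(name, ncol, nrow_) {
    i <- grep(paste0("^", name), lines)
    if (!length(i)) return(NULL)
    block <- lines[(i[1] + 1):length(lines)]
    block <- block[nzchar(trimws(sub("#.*$", "", block)))]
    block <- utils::head(block, nrow_)
    t(vapply(block, function(l)
      as.numeric(strsplit(trimws(sub("#.*$", "", l)), "[[:space:]]+")[[1]][seq_len(ncol)]),
      numeric(ncol), USE.NAMES = FALSE))
  }
  atoms <- section("Atoms", 7, n)
  if (is.null(atoms) || nrow(atoms) != n || anyNA(atoms))
    stop("malformed LAMMPS data file: bad Atoms section")
  ord <- order(atoms[, 1])
  atoms <- atoms[ord, , drop = FALSE]
  type <- typemap[atoms[, 3]]
  if (anyNA(type)) stop("malformed LAMMPS data file: type map mismatch")
  sys <- empty_system(box)
  sys$positions <- atoms[, 5:7, drop = FALSE] / 10
  dimnames(sys$positions) <- NULL
  sys$type <- type
  sys$charge <- atoms[, 4]
  sys$mass <- bead_property(ff, type, "mass")
  sys$molecule <- as.integer(atoms[, 2])
  if (nb > 0) {
    b <- section("Bonds", 4, nb)
    if (is.null(b) || nrow(b) != nb)
      stop("malformed LAMMPS data file: bad Bonds section")
    sys$bonds <- data.frame(i = as.integer(b[, 3]), j = as.integer(b[, 4]),
                            type_i = type[b[, 3]], type_j = type[b[, 4]])
  }
  if (na_ > 0) {
    a <- section("Angles", 5, na_)
    if (is.null(a) || nrow(a) != na_)
      stop("malformed LAMMPS data file: bad Angles section")
    sys$angles <- data.frame(i = as.integer(a[, 3]), j = as.integer(a[, 4]),
                             k = as.integer(a[, 5]),
                             type_i = type[a[, 3]], type_j = type[a[, 4]],
                             type_k = type[a[, 5]])
  }
  sys$rigid_groups <- rigid_groups
  sys
}

#' Write a trajectory (or single configuration) as multi-frame XYZ
#'
#' Coordinates in nm at 1e-5 nm precision; the comment line carries the
#' box and the frame time: `box <lx> <ly> <lz> time <t>`.
#'
#' @param traj A [cg_trajectory] or a `cg_system` (one frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "cg_system"))
    traj <- cg_trajectory(array(traj$positions,
                                dim = c(nrow(traj$positions), 3, 1)),
                          traj$box, times = 0, type = traj$type,
                          mass = traj$mass)
  n <- dim(traj$coords)[1]
  labels <- if (is.null(traj$type)) rep("X", n) else traj$type
  con <- file(path, "w")
  on.exit(close(con))
  for (fidx in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("%d", n),
                 sprintf("box %.5f %.5f %.5f time %.6f",
                         traj$box[1], traj$box[2], traj$box[3],
                         traj$times[fidx]),
                 sprintf("%s %.5f %.5f %.5f", labels,
                         traj$coords[, 1, fidx],
                         traj$coords[, 2, fidx],
                         traj$coords[, 3, fidx])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory written by [write_xyz]
#'
#' @param path File path.
#' @return A [cg_trajectory].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(); box <- NULL; type <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ file at line ", i)
    cm <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(cm) >= 4 && cm[1] == "box")
      box <- as.numeric(cm[2:4])
    t <- if (length(cm) >= 6 && cm[5] == "time") as.numeric(cm[6])
         else length(times) + 1
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (is.null(type)) type <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t)
    i <- i + 2L + n
  }
  if (is.null(box)) stop("XYZ file has no box comment line")
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                          length(frames)))
  cg_trajectory(coords, box, times = times, type = type)
}

#' Read a LAMMPS dump trajectory
#'
#' Parses the standard text dump (`ITEM: TIMESTEP` / `NUMBER OF ATOMS` /
#' `BOX BOUNDS` / `ATOMS` with at least `id x y z` columns). Dump
#' coordinates are assumed to be in Angstrom and are scaled to nm.
#'
#' @param path File path.
#' @param scale Coordinate scale factor to nm. Default 0.1.
#' @return A [cg_trajectory] (frames ordered by atom id).
#' @export
read_lammps_dump <- function(path, scale = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  its <- grep("^ITEM: TIMESTEP", lines)
  if (!length(its)) stop("malformed LAMMPS dump: no TIMESTEP item")
  frames <- list(); times <- numeric(); box <- NULL; type <- NULL
  for (s in seq_along(its)) {
    i <- its[s]
    t <- as.numeric(lines[i + 1])
    na_line <- grep("^ITEM: NUMBER OF ATOMS", lines[i:length(lines)])[1] + i - 1
    n <- as.integer(lines[na_line + 1])
    bb <- grep("^ITEM: BOX BOUNDS", lines[i:length(lines)])[1] + i - 1
    bounds <- t(vapply(lines[bb + 1:3], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]][1:2]),
      numeric(2), USE.NAMES = FALSE))
    box <- (bounds[, 2] - bounds[, 1]) * scale
    ai <- grep("^ITEM: ATOMS", lines[i:length(lines)])[1] + i - 1
    cols <- strsplit(sub("^ITEM: ATOMS ", "", lines[ai]), "[[:space:]]+")[[1]]
    need <- match(c("id", "x", "y", "z"), cols)
    if (anyNA(need)) stop("LAMMPS dump lacks id/x/y/z columns")
    block <- lines[ai + seq_len(n)]
    vals <- t(vapply(strsplit(trimws(block), "[[:space:]]+"),
                     function(p) as.numeric(p[need]), numeric(4)))
    ord <- order(vals[, 1])
    frames[[s]] <- vals[ord, 2:4, drop = FALSE] * scale
    times <- c(times, t)
    tcol <- match("type", cols)
    if (!is.na(tcol) && is.null(type))
      type <- vapply(strsplit(trimws(block), "[[:space:]]+"),
                     `[[`, "", tcol)[ord]
  }
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                          length(frames)))
  cg_trajectory(coords, box, times = times, type = type)
}

#' @export
as.data.frame.rdf_curve <- function(x, ...) {
  data.frame(r = x$r, g = x$g)
}

#' @export
as.data.frame.aggregation_trace <- function(x, ...) {
  d <- data.frame(time = x$times, fraction = x$fraction)
  if (!is.null(x$n_clusters)) d$n_clusters <- x$n_clusters
  d
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(r = x$r, F = x$F, sigma_F = x$sigma_F)
}
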