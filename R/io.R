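#' Read a multi-frame trajectory file
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` records; read through
#' bio3d, Angstrom converted to nm), multi-frame GRO (concatenated frames,
#' already in nm) and multi-frame XYZ (Angstrom converted to nm). A reader
#' plug-in for any other (e.g. binary) format can be supplied as a function
#' `path -> list(atoms = <data frame>, coords = <list of nm matrices>,
#' times = <numeric>)`.
#'
#' @param path Path to the trajectory file.
#' @param format One of `"pdb"`, `"gro"`, `"xyz"`, or a reader function.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb", "gro", "xyz")) {
  if (is.function(format)) {
    parts <- format(path)
    return(trajectory(parts$atoms, parts$coords, parts$times))
  }
  format <- match.arg(format)
  assert_that(file.exists(path), paste("no such file:", path))
  switch(format,
    pdb = read_trajectory_pdb(path),
    gro = read_trajectory_gro(path),
    xyz = read_trajectory_xyz(path)
  )
}

# Map atom names to element symbols and masses (standard atomic weights)
# through bio3d's lookup tables; unknown names fall back to carbon with a
# warning from bio3d's rescue path.
.element_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      cache <<- e$elements
    }
    cache
  }
})

atom_masses <- function(atom_names) {
  ele <- suppressWarnings(bio3d::atom2ele(atom_names, rescue = TRUE))
  tab <- .element_table()
  mass <- tab$mass[match(ele, tab$symb)]
  if (anyNA(mass))
    stop("unknown element(s): ", paste(unique(ele[is.na(mass)]), collapse = ", "),
         call. = FALSE)
  list(element = ele, mass = mass)
}

read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    # pre-scan so a malformed model can be reported by frame index
    model_of <- cumsum(model_starts)
    counts <- table(model_of[is_atom])
    if (length(unique(as.integer(counts))) > 1) {
      bad <- as.integer(names(counts)[counts != as.integer(counts)[1]])[1]
      stop(sprintf("frame %d has %d atoms; expected %d",
                   bad - 1L, counts[[as.character(bad)]], as.integer(counts)[1]),
           call. = FALSE)
    }
  }
  if (!any(is_atom)) stop("no ATOM/HETATM records found", call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(pdb$atom)
  em <- atom_masses(pdb$atom$elety)
  atoms <- tibble::tibble(
    atom_index = seq_len(na),
    atom_name = pdb$atom$elety,
    element = em$element,
    mass = em$mass,
    residue_id = as.integer(pdb$atom$resno),
    res_name = pdb$atom$resid
  )
  coords <- lapply(seq_len(nf), function(k)
    matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE) * 0.1)  # Angstrom -> nm
  trajectory(atoms, coords)
}

read_trajectory_gro <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  times <- numeric()
  atoms <- NULL
  frame_i <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    title <- lines[pos]
    na <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(na)) stop(sprintf("frame %d: bad atom count line", frame_i), call. = FALSE)
    if (pos + 1L + na + 1L > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atoms)", frame_i, na), call. = FALSE)
    block <- lines[(pos + 2L):(pos + 1L + na)]
    resno <- as.integer(substr(block, 1, 5))
    resname <- trimws(substr(block, 6, 10))
    aname <- trimws(substr(block, 11, 15))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    if (is.null(atoms)) {
      em <- atom_masses(aname)
      atoms <- tibble::tibble(
        atom_index = seq_len(na), atom_name = aname, element = em$element,
        mass = em$mass, residue_id = resno, res_name = resname
      )
    } else if (na != nrow(atoms)) {
      stop(sprintf("frame %d has %d atoms; expected %d", frame_i, na, nrow(atoms)),
           call. = FALSE)
    }
    t_match <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    times <- c(times, if (length(t_match) == 2) as.numeric(t_match[2]) else frame_i)
    frames[[frame_i + 1L]] <- xyz
    frame_i <- frame_i + 1L
    pos <- pos + na + 3L  # title + count + atoms + box line
  }
  if (frame_i == 0L) stop("empty GRO file", call. = FALSE)
  trajectory(atoms, frames, times)
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  atoms <- NULL
  frame_i <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na)) stop(sprintf("frame %d: bad atom count line", frame_i), call. = FALSE)
    if (pos + 1L + na > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atoms)", frame_i, na), call. = FALSE)
    block <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + na)]), "\\s+")
    el <- vapply(block, `[[`, "", 1L)
    xyz <- t(vapply(block, function(f) as.numeric(f[2:4]), numeric(3))) * 0.1  # Angstrom -> nm
    if (is.null(atoms)) {
      em <- atom_masses(el)
      atoms <- tibble::tibble(
        atom_index = seq_len(na), atom_name = el, element = em$element,
        mass = em$mass, residue_id = 1L, res_name = "MOL"
      )
    } else if (na != nrow(atoms)) {
      stop(sprintf("frame %d has %d atoms; expected %d", frame_i, na, nrow(atoms)),
           call. = FALSE)
    }
    frames[[frame_i + 1L]] <- xyz
    frame_i <- frame_i + 1L
    pos <- pos + na + 2L
  }
  if (frame_i == 0L) stop("empty XYZ file", call. = FALSE)
  trajectory(atoms, frames)
}

#' Write a trajectory to a multi-frame file
#'
#' PDB output goes through bio3d (one `MODEL` per frame, nm converted to
#' Angstrom with three decimals, i.e. 1e-3 Angstrom precision). GRO keeps nm;
#' XYZ converts to Angstrom.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format One of `"pdb"`, `"gro"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "gro", "xyz")) {
  format <- match.arg(format)
  a <- traj$atoms
  resn <- if ("res_name" %in% names(a)) a$res_name else rep("RES", nrow(a))
  if (format == "pdb") {
    xyz <- do.call(rbind, lapply(traj$coords, function(m) as.vector(t(m)) * 10))
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$residue_id,
                     resid = resn, elety = a$atom_name)
  } else if (format == "gro") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(traj$coords)) {
      writeLines(sprintf("frame %d t= %.6f", k - 1L, traj$times[k]), con)
      writeLines(sprintf("%5d", nrow(a)), con)
      m <- traj$coords[[k]]
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$residue_id, substr(resn, 1, 5), substr(a$atom_name, 1, 5),
                         a$atom_index %% 100000L, m[, 1], m[, 2], m[, 3]), con)
      writeLines("   0.000   0.000   0.000", con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(traj$coords)) {
      writeLines(sprintf("%d", nrow(a)), con)
      writeLines(sprintf("frame %d", k - 1L), con)
      m <- traj$coords[[k]] * 10
      writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", a$element, m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' Read / write a residue map as CSV
#'
#' Columns: `residue_id`, `label`, `strand`.
#'
#' @param path CSV path.
#' @return [read_residue_map()] returns a [residue_map()].
#' @export
read_residue_map <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  residue_map(d$residue_id, d$label, d$strand)
}

#' @rdname read_residue_map
#' @param rmap A [residue_map()].
#' @export
write_residue_map <- function(rmap, path) {
  write.csv(as.data.frame(rmap), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a dye selection configuration (YAML)
#'
#' The YAML file holds a `dyes:` list; each entry has `name`, `residue_id`,
#' `squarate_carbons` (exactly 4 atom indices), `ring_far` and `ring_near`
#' (>= 5 atom indices each, the terminal benzene rings; `ring_far` is the
#' ring furthest from the linker, fixed by covalent topology rather than
#' inferred per frame). Atom indices are 1-based.
#'
#' @param path YAML path.
#' @return [read_selection_config()] returns a [selection_config()].
#' @export
read_selection_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(selection_config, lapply(y$dyes, function(d)
    dye_selection(name = d$name, residue_id = d$residue_id,
                  squarate_carbons = d$squarate_carbons,
                  ring_far = d$ring_far, ring_near = d$ring_near)))
}

#' @rdname read_selection_config
#' @param sel A [selection_config()].
#' @export
write_selection_config <- function(sel, path) {
  yaml::write_yaml(list(dyes = lapply(sel, function(d) list(
    name = d$name, residue_id = d$residue_id,
    squarate_carbons = d$squarate_carbons,
    ring_far = d$ring_far, ring_near = d$ring_near
  ))), path)
  invisible(path)
}
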