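# Plain-text readers and writers: flat parameter tables, Tinker-style XYZ
# with connectivity (single- and multi-frame), and a minimal PDB reader.

#' Read a flat force-field parameter table
#'
#' The format is line-oriented plain text; `#` starts a comment.  Records:
#' \preformatted{
#' atom  <type_label> <role> <charge> <lj_epsilon> <lj_rmin_half> <mass>
#' bond  <label_i> <label_j> <kb> <b0>
#' angle <label_i> <label_j> <label_k> <ktheta> <theta0_deg>
#' }
#' with `role` one of `protein`, `water_O`, `water_H`; `theta0` is given in
#' degrees and converted to radians.
#'
#' @param path file path.
#' @return list with data.frames `atoms`, `bonds`, `angles`.
#' @export
read_param_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  atoms <- list(); bonds <- list(); angles <- list()
  for (k in seq_along(lines)) {
    tok <- strsplit(lines[k], "[[:space:]]+")[[1L]]
    kind <- tok[1L]
    if (kind == "atom" && length(tok) == 7L) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        type_label = tok[2L], role = tok[3L],
        charge = as.numeric(tok[4L]), lj_epsilon = as.numeric(tok[5L]),
        lj_rmin_half = as.numeric(tok[6L]), mass = as.numeric(tok[7L]))
    } else if (kind == "bond" && length(tok) == 5L) {
      bonds[[length(bonds) + 1L]] <- data.frame(
        label_i = tok[2L], label_j = tok[3L],
        kb = as.numeric(tok[4L]), b0 = as.numeric(tok[5L]))
    } else if (kind == "angle" && length(tok) == 6L) {
      angles[[length(angles) + 1L]] <- data.frame(
        label_i = tok[2L], label_j = tok[3L], label_k = tok[4L],
        ktheta = as.numeric(tok[5L]),
        theta0 = as.numeric(tok[6L]) * pi / 180)
    } else {
      stop("parameter parse error at line ", k, ": '", lines[k], "'")
    }
  }
  list(atoms = if (length(atoms)) do.call(rbind, atoms) else NULL,
       bonds = if (length(bonds)) do.call(rbind, bonds) else
         data.frame(label_i = character(), label_j = character(),
                    kb = numeric(), b0 = numeric()),
       angles = if (length(angles)) do.call(rbind, angles) else
         data.frame(label_i = character(), label_j = character(),
                    label_k = character(), ktheta = numeric(),
                    theta0 = numeric()))
}

#' Write a system (or an ensemble) as Tinker-style XYZ with connectivity
#'
#' Each frame is a block: a header line with the atom count and a title,
#' then one line per atom with index, type label, coordinates (9 significant
#' digits) and the indices of bonded neighbors.
#'
#' @param sys a [molecular_system()].
#' @param path output path.
#' @param frames optional list of coordinate matrices; if given, one block
#'   per frame is written, otherwise the system's own coordinates.
#' @param title header comment.
#' @export
write_xyz <- function(sys, path, frames = NULL, title = "cgdelta") {
  nbr <- vector("list", nrow(sys$atoms))
  for (r in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds$i[r]; j <- sys$bonds$j[r]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  if (is.null(frames)) frames <- list(sys$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (x in frames) {
    writeLines(sprintf("%6d  %s", nrow(sys$atoms), title), con)
    ln <- vapply(seq_len(nrow(sys$atoms)), function(a) {
      sprintf("%6d  %-10s %15.9f %15.9f %15.9f  %s", a,
              sys$atoms$type_label[a], x[a, 1L], x[a, 2L], x[a, 3L],
              paste(sort(nbr[[a]]), collapse = " "))
    }, character(1L))
    writeLines(ln, con)
  }
  invisible(path)
}

#' Read a Tinker-style XYZ file (coordinates, labels, connectivity)
#'
#' @param path file path.
#' @param all_frames if TRUE, return every block in the file.
#' @return a skeleton list with `n`, `type_labels`, `coords`, `bonds`
#'   (2-column index matrix) and, when `all_frames`, `frames` (list of
#'   coordinate matrices).
#' @export
read_xyz <- function(path, all_frames = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty XYZ file")
  parse_header <- function(ln, lineno) {
    n <- suppressWarnings(as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1L]][1L]))
    if (is.na(n) || n < 1L)
      stop("parse error at line ", lineno, ": bad atom count")
    n
  }
  pos <- 1L
  frames <- list()
  skel <- NULL
  while (pos <= length(lines)) {
    n <- parse_header(lines[pos], pos)
    if (pos + n > length(lines))
      stop("parse error: truncated frame at line ", pos)
    coords <- matrix(0, n, 3L)
    labels <- character(n)
    bond_l <- list()
    for (a in seq_len(n)) {
      tok <- strsplit(trimws(lines[pos + a]), "[[:space:]]+")[[1L]]
      if (length(tok) < 5L)
        stop("parse error at line ", pos + a, ": expected index, label, x, y, z")
      xyz <- suppressWarnings(as.numeric(tok[3:5]))
      if (anyNA(xyz))
        stop("parse error at line ", pos + a, ": bad coordinates")
      labels[a] <- tok[2L]
      coords[a, ] <- xyz
      if (length(tok) > 5L) {
        nb <- suppressWarnings(as.integer(tok[6:length(tok)]))
        if (anyNA(nb))
          stop("parse error at line ", pos + a, ": bad connectivity")
        nb <- nb[nb > a]     # record each edge once
        if (length(nb)) bond_l[[length(bond_l) + 1L]] <- cbind(a, nb)
      }
    }
    if (is.null(skel))
      skel <- list(n = n, type_labels = labels, coords = coords,
                   bonds = if (length(bond_l)) do.call(rbind, bond_l)
                           else matrix(integer(), 0L, 2L))
    frames[[length(frames) + 1L]] <- coords
    pos <- pos + n + 1L
    if (!all_frames) break
  }
  if (all_frames) skel$frames <- frames
  skel
}

#' Build a molecular system from an XYZ skeleton and a parameter table
#'
#' Atom parameters are looked up by type label; roles come from the
#' parameter table, with the two hydrogens of each water assigned first- and
#' second-hydrogen roles in file order.  Molecules are the connected
#' components of the bond graph; bond and angle constants are instantiated
#' from the label-keyed tables.
#'
#' @param skel a [read_xyz()] skeleton.
#' @param params a [read_param_file()] table.
#' @return a [molecular_system()].
#' @export
system_from_xyz <- function(skel, params) {
  pa <- params$atoms
  hit <- match(skel$type_labels, pa$type_label)
  if (anyNA(hit))
    stop("parameter error: no parameters for type label(s) ",
         paste(unique(skel$type_labels[is.na(hit)]), collapse = ", "))
  role_raw <- pa$role[hit]
  # connected components of the bond graph = molecules
  n <- skel$n
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(skel$bonds))) {
      i <- skel$bonds[r, 1L]; j <- skel$bonds[r, 2L]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  molecule <- match(comp, unique(comp))
  role <- role_raw
  for (m in unique(molecule)) {
    mem <- which(molecule == m)
    hs <- mem[role_raw[mem] == "water_H"]
    if (length(hs) == 2L) {
      role[hs[1L]] <- "water_H1"
      role[hs[2L]] <- "water_H2"
    } else if (length(hs) > 0L) {
      stop("topology error: molecule ", m, " has ", length(hs),
           " water hydrogens")
    }
  }
  atoms <- data.frame(element = substr(skel$type_labels, 1L, 1L),
                      type_label = skel$type_labels,
                      charge = pa$charge[hit],
                      lj_epsilon = pa$lj_epsilon[hit],
                      lj_rmin_half = pa$lj_rmin_half[hit],
                      mass = pa$mass[hit],
                      role = role, molecule = molecule)
  lab <- skel$type_labels
  bonds <- NULL
  if (nrow(skel$bonds)) {
    key <- paste(lab[skel$bonds[, 1L]], lab[skel$bonds[, 2L]])
    tkey <- paste(params$bonds$label_i, params$bonds$label_j)
    tkey_r <- paste(params$bonds$label_j, params$bonds$label_i)
    row <- match(key, tkey)
    row[is.na(row)] <- match(key, tkey_r)[is.na(row)]
    if (anyNA(row))
      stop("parameter error: no bond parameters for ",
           paste(unique(key[is.na(row)]), collapse = "; "))
    bonds <- data.frame(i = skel$bonds[, 1L], j = skel$bonds[, 2L],
                        kb = params$bonds$kb[row], b0 = params$bonds$b0[row])
  }
  # angles: every neighbor pair around a vertex
  angles <- list()
  if (!is.null(bonds) && nrow(params$angles)) {
    nbr <- vector("list", n)
    for (r in seq_len(nrow(bonds))) {
      nbr[[bonds$i[r]]] <- c(nbr[[bonds$i[r]]], bonds$j[r])
      nbr[[bonds$j[r]]] <- c(nbr[[bonds$j[r]]], bonds$i[r])
    }
    akey <- paste(params$angles$label_i, params$angles$label_j,
                  params$angles$label_k)
    akey_r <- paste(params$angles$label_k, params$angles$label_j,
                    params$angles$label_i)
    for (v in seq_len(n)) {
      ns <- nbr[[v]]
      if (length(ns) < 2L) next
      cmb <- utils::combn(sort(ns), 2L)
      for (cix in seq_len(ncol(cmb))) {
        i <- cmb[1L, cix]; k <- cmb[2L, cix]
        key <- paste(lab[i], lab[v], lab[k])
        row <- match(key, akey)
        if (is.na(row)) row <- match(key, akey_r)
        if (is.na(row))
          stop("parameter error: no angle parameters for ", key)
        angles[[length(angles) + 1L]] <- data.frame(
          i = i, j = v, k = k,
          ktheta = params$angles$ktheta[row],
          theta0 = params$angles$theta0[row])
      }
    }
  }
  molecular_system(atoms, skel$coords, bonds,
                   if (length(angles)) do.call(rbind, angles) else NULL)
}

#' Minimal PDB reader (coordinates and elements only)
#'
#' Parses ATOM/HETATM records by fixed columns.
#'
#' @param path file path.
#' @return list with `coords` (n x 3) and `elements`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  rec <- substr(lines, 1L, 6L)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(sel)) stop("parse error: no ATOM/HETATM records")
  x <- as.numeric(substr(lines[sel], 31L, 38L))
  y <- as.numeric(substr(lines[sel], 39L, 46L))
  z <- as.numeric(substr(lines[sel], 47L, 54L))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("parse error: bad coordinates in ATOM/HETATM record")
  el <- trimws(substr(lines[sel], 77L, 78L))
  blank <- !nzchar(el)
  el[blank] <- substr(trimws(substr(lines[sel][blank], 13L, 16L)), 1L, 1L)
  list(coords = cbind(x, y, z), elements = el)
}
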