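# Readers and writers for the ligand PDBQT subset and the AutoDock grid-map
# text dialect.  Parsers reject malformed records (with line numbers) rather
# than silently skipping them.

parse_stop <- function(lineno, msg) {
  stop("PDBQT parse error at line ", lineno, ": ", msg, call. = FALSE)
}

num_or_stop <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) parse_stop(lineno, paste0("non-numeric ", what, " '",
                                          trimws(s), "'"))
  v
}

#' Read a ligand PDBQT file
#'
#' Parses the ligand subset of the PDBQT dialect: `ATOM`/`HETATM` records
#' with partial charges and AutoDock atom types, the `ROOT`/`ENDROOT` rigid
#' core, nested `BRANCH`/`ENDBRANCH` pairs defining the torsion tree, and
#' `TORSDOF`.  Receptor files and other record types are out of scope.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a `ligand_topology`.
#' @export
read_pdbqt <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  atoms <- list()
  serials <- integer(0)
  root <- integer(0)
  in_root <- FALSE
  root_seen <- FALSE
  branch_stack <- list()   # each: list(bond = c(a, b), moves = integer())
  branches <- list()
  branch_order <- integer(0)
  torsdof <- NA_integer_
  last_serial <- NA_integer_

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- trimws(substr(line, 1, 9))
    if (startsWith(line, "ATOM") || startsWith(line, "HETATM")) {
      if (nchar(line) < 54) parse_stop(ln, "truncated ATOM record")
      serial <- as.integer(num_or_stop(substr(line, 7, 11), ln, "serial"))
      name <- trimws(substr(line, 13, 16))
      x <- num_or_stop(substr(line, 31, 38), ln, "x")
      y <- num_or_stop(substr(line, 39, 46), ln, "y")
      z <- num_or_stop(substr(line, 47, 54), ln, "z")
      charge <- if (nchar(line) >= 76)
        num_or_stop(substr(line, 71, 76), ln, "charge") else 0
      type <- if (nchar(line) >= 78) trimws(substr(line, 78, 79)) else ""
      if (type == "") type <- trimws(substr(name, 1, 1))
      element <- sub("[0-9]+$", "", substr(name, 1, 1))
      atoms[[length(atoms) + 1L]] <- data.frame(
        id = serial, name = name, element = element, type = type,
        charge = charge, x = x, y = y, z = z)
      serials <- c(serials, serial)
      last_serial <- serial
      if (in_root) root <- c(root, serial)
      if (length(branch_stack)) {
        for (bi in seq_along(branch_stack)) {
          bond <- branch_stack[[bi]]$bond
          if (serial != bond[2]) {
            branch_stack[[bi]]$moves <- c(branch_stack[[bi]]$moves, serial)
          }
        }
      }
    } else if (startsWith(line, "ROOT")) {
      if (root_seen) parse_stop(ln, "duplicate ROOT")
      in_root <- TRUE
      root_seen <- TRUE
    } else if (startsWith(line, "ENDROOT")) {
      if (!in_root) parse_stop(ln, "ENDROOT without ROOT")
      in_root <- FALSE
    } else if (startsWith(line, "BRANCH")) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) != 3) parse_stop(ln, "BRANCH needs two atom serials")
      a <- suppressWarnings(as.integer(f[2]))
      b <- suppressWarnings(as.integer(f[3]))
      if (is.na(a) || is.na(b)) parse_stop(ln, "non-numeric BRANCH serials")
      branch_stack[[length(branch_stack) + 1L]] <-
        list(bond = c(a, b), moves = integer(0))
    } else if (startsWith(line, "ENDBRANCH")) {
      if (!length(branch_stack)) parse_stop(ln, "unbalanced ENDBRANCH")
      f <- strsplit(trimws(line), "\\s+")[[1]]
      top <- branch_stack[[length(branch_stack)]]
      if (length(f) == 3) {
        a <- suppressWarnings(as.integer(f[2]))
        b <- suppressWarnings(as.integer(f[3]))
        if (!is.na(a) && !is.na(b) && any(top$bond != c(a, b))) {
          parse_stop(ln, "ENDBRANCH does not match the open BRANCH")
        }
      }
      branch_stack[[length(branch_stack)]] <- NULL
      branches[[length(branches) + 1L]] <- top
    } else if (startsWith(line, "TORSDOF")) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      torsdof <- suppressWarnings(as.integer(f[2]))
      if (is.na(torsdof)) parse_stop(ln, "non-numeric TORSDOF")
    } else if (rec == "" || startsWith(line, "REMARK") ||
               startsWith(line, "MODEL") || startsWith(line, "ENDMDL") ||
               startsWith(line, "TER") || startsWith(line, "END")) {
      # tolerated
    } else {
      parse_stop(ln, paste0("unsupported record '", rec, "'"))
    }
  }
  if (length(branch_stack)) {
    stop("PDBQT parse error: ", length(branch_stack),
         " unclosed BRANCH record(s)", call. = FALSE)
  }
  if (!root_seen) stop("PDBQT parse error: missing ROOT", call. = FALSE)
  if (!length(atoms)) stop("PDBQT parse error: no atoms", call. = FALSE)
  atoms <- do.call(rbind, atoms)
  if (is.na(torsdof)) torsdof <- length(branches)
  # file order is leaf-closed-first; decode wants root-outward ordering:
  # sort branches so a parent (whose moving set contains a child's bond
  # atoms) comes before the child.  Larger moving sets are closer to root.
  if (length(branches) > 1L) {
    branches <- branches[order(-vapply(branches, function(b)
      length(b$moves), integer(1)))]
  }
  ligand_topology(atoms, bonds = NULL, root = root, branches = branches,
                  torsdof = torsdof)
}

#' Write a ligand PDBQT file
#'
#' Emits the decoded coordinates of `genome` in fixed-width PDB columns
#' (3-decimal coordinates), preserving charges, atom types and the torsion
#' tree records so the file round-trips through [read_pdbqt()].
#'
#' @param topo a `ligand_topology`.
#' @param genome pose genome (defaults to the identity pose).
#' @param path optional output path; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when written to a file).
#' @export
write_pdbqt <- function(topo, genome = identity_genome(length(topo$branches)),
                        path = NULL) {
  coords <- decode_pose(genome, topo)
  at <- topo$atoms
  atom_line <- function(i) {
    sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            at$id[i], substr(at$name[i], 1, 4), coords[i, 1], coords[i, 2],
            coords[i, 3], 1, 0, at$charge[i], at$type[i])
  }
  in_root <- at$id %in% topo$root
  lines <- c("REMARK ligand written by higadock", "ROOT",
             vapply(which(in_root), atom_line, character(1)), "ENDROOT")
  # emit branches root-outward with proper nesting
  emitted <- at$id[in_root]
  emit_branch <- function(bi) {
    br <- topo$branches[[bi]]
    own <- setdiff(br$moves, unlist(lapply(topo$branches[-seq_len(bi)],
      function(b2) if (all(b2$moves %in% br$moves)) b2$moves else NULL)))
    out <- sprintf("BRANCH %d %d", br$bond[1], br$bond[2])
    # the branch's frame atom (bond[2]) plus atoms it moves directly
    block_ids <- c(br$bond[2], own)
    block_ids <- block_ids[!block_ids %in% emitted]
    emitted <<- c(emitted, block_ids)
    out <- c(out, vapply(match(block_ids, at$id), atom_line, character(1)))
    # nested branches: those whose moving set is a subset of ours
    kids <- which(vapply(seq_along(topo$branches), function(j) {
      j > bi && all(topo$branches[[j]]$moves %in% br$moves)
    }, logical(1)))
    direct <- kids[vapply(kids, function(j) {
      !any(vapply(kids, function(k2) {
        k2 != j && all(topo$branches[[j]]$moves %in%
                       topo$branches[[k2]]$moves) &&
          length(topo$branches[[k2]]$moves) > length(topo$branches[[j]]$moves)
      }, logical(1)))
    }, logical(1))]
    for (j in direct) out <- c(out, emit_branch(j))
    c(out, sprintf("ENDBRANCH %d %d", br$bond[1], br$bond[2]))
  }
  top_level <- which(vapply(seq_along(topo$branches), function(j) {
    !any(vapply(seq_along(topo$branches), function(k2) {
      k2 != j && all(topo$branches[[j]]$moves %in%
                     topo$branches[[k2]]$moves) &&
        length(topo$branches[[k2]]$moves) > length(topo$branches[[j]]$moves)
    }, logical(1)))
  }, logical(1)))
  for (j in top_level) lines <- c(lines, emit_branch(j))
  lines <- c(lines, sprintf("TORSDOF %d", topo$torsdof))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read an AutoDock grid map file
#'
#' Header: `GRID_PARAMETER_FILE`, `GRID_DATA_FILE`, `MACROMOLECULE`,
#' `SPACING s`, `NELEMENTS nx ny nz` (even element counts; points per axis
#' are `n + 1`), `CENTER cx cy cz`, followed by one energy value per line
#' in x-fastest, then y, then z order.
#'
#' @param path file path, or lines via `text`.
#' @param text optional character vector of lines.
#' @return list with `lattice` (3-D array, x index fastest), `center`,
#'   `spacing`, `npts`.
#' @export
read_map <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  spacing <- NA_real_; nelements <- NULL; center <- NULL
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- f[1]
    if (is.na(key) || key == "") { i <- i + 1L; next }
    if (key == "SPACING") {
      spacing <- as.numeric(f[2])
    } else if (key == "NELEMENTS") {
      nelements <- as.integer(f[2:4])
    } else if (key == "CENTER") {
      center <- as.numeric(f[2:4])
    } else if (key %in% c("GRID_PARAMETER_FILE", "GRID_DATA_FILE",
                          "MACROMOLECULE")) {
      # metadata, ignored
    } else {
      break  # first data value
    }
    i <- i + 1L
  }
  if (is.na(spacing) || is.null(nelements) || is.null(center)) {
    stop("map header incomplete: SPACING, NELEMENTS and CENTER are required")
  }
  npts <- nelements + 1L
  data_lines <- trimws(lines[i:length(lines)])
  data_lines <- data_lines[data_lines != ""]
  vals <- suppressWarnings(as.numeric(data_lines))
  if (anyNA(vals)) stop("non-numeric map value encountered")
  expected <- prod(npts)
  if (length(vals) != expected) {
    stop("map value count mismatch: expected ", expected, ", found ",
         length(vals))
  }
  lattice <- array(vals, dim = npts)  # column-major = x fastest
  list(lattice = lattice, center = center, spacing = spacing, npts = npts)
}

#' Write an AutoDock grid map file
#'
#' @param lattice 3-D array (x index fastest).
#' @param center length-3 box center.
#' @param spacing grid spacing.
#' @param path optional output path; lines returned when `NULL`.
#' @param digits printed precision of the values.
#' @return character vector of lines (invisibly when written to a file).
#' @export
write_map <- function(lattice, center, spacing, path = NULL, digits = 6) {
  npts <- dim(lattice)
  lines <- c(
    "GRID_PARAMETER_FILE none",
    "GRID_DATA_FILE none",
    "MACROMOLECULE none",
    sprintf("SPACING %.4f", spacing),
    sprintf("NELEMENTS %d %d %d", npts[1] - 1L, npts[2] - 1L, npts[3] - 1L),
    sprintf("CENTER %.4f %.4f %.4f", center[1], center[2], center[3]),
    formatC(as.vector(lattice), digits = digits, format = "g")
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a directory of grid maps as a `grid_map_set`
#'
#' Expects files named `<type>.map` plus an electrostatics map `e.map`
#' (optional).  All maps must share geometry.
#'
#' @param dir directory containing the map files.
#' @return a `grid_map_set`.
#' @export
read_map_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.map$", full.names = TRUE)
  if (!length(files)) stop("no .map files found in ", dir)
  maps <- list(); emap <- NULL; geom <- NULL
  for (f in files) {
    m <- read_map(f)
    if (is.null(geom)) {
      geom <- m
    } else if (!isTRUE(all.equal(geom$center, m$center)) ||
               geom$spacing != m$spacing || any(geom$npts != m$npts)) {
      stop("map geometry mismatch in ", basename(f))
    }
    ty <- sub("\\.map$", "", basename(f))
    if (ty == "e") emap <- m$lattice else maps[[ty]] <- m$lattice
  }
  grid_map_set(geom$center, geom$spacing, geom$npts, maps, emap)
}

#' Write a `grid_map_set` to a directory
#' @param maps a `grid_map_set`.
#' @param dir output directory (created if missing).
#' @export
write_map_set <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ty in names(maps$maps)) {
    write_map(maps$maps[[ty]], maps$center, maps$spacing,
              file.path(dir, paste0(ty, ".map")))
  }
  write_map(maps$emap, maps$center, maps$spacing, file.path(dir, "e.map"))
  invisible(dir)
}
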